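#' Joint inference of the free-ribosome trajectory and per-transcript constants
#'
#' Minimizes the weighted sum of squared log-residuals
#' \deqn{\sum_i \sum_c w_{ic}\,(\log \lambda^{obs}_{ic} -
#'       \log\frac{K_{1i} R_c}{K_{2i} + R_c})^2}
#' over per-transcript \{K1, K2\} and per-condition R, under positivity
#' (log-parameterization) and a gauge convention resolving the
#' (R, K2) -> (cR, cK2) scale non-identifiability. A second exact
#' invariance (the reciprocal shift 1/R -> 1/R + t, which preserves every
#' prediction) is resolved by convention: the fit is transformed so the
#' largest K2 sits at the finite cap `k2_max_factor * max R`, i.e. the most
#' undersaturated transcript is reported as effectively linear in R (its
#' K1/K2 ratio is the identified quantity). The solver alternates
#' exact separable sub-problems: per-id profile fits given R (K1 closed-form
#' given K2; 1-D search over log K2) and per-condition 1-D solves given the
#' constants, iterated to a relative objective change below `tol`, with
#' seeded multistart. Log-scale residuals reflect the multiplicative noise
#' of the assays; `scale = "linear"` switches to linear-scale residuals.
#'
#' @param data data frame with columns `id`, `condition`, `mu`, `lambda`
#'   (replicate rows allowed) or `id`, `condition`, `mu`, `P`, `m`
#'   (lambda computed as `mu * P / m`).
#' @param gauge `"ref_ratio"` (K1/K2 of `ref_id` scaled to 1) or
#'   `"anchor_slowest"` (R at the slowest condition = 1).
#' @param ref_id reference id for the `ref_ratio` gauge (default the first).
#' @param n_starts multistart count (default 20).
#' @param seed RNG seed for the multistart initializations.
#' @param scale `"log"` (default) or `"linear"` residuals.
#' @param tol relative objective-change convergence tolerance.
#' @param max_iter maximum alternating sweeps.
#' @param k2_max_factor upper bound on K2 as a multiple of max R (keeps
#'   undersaturated fits finite; report K1/K2 for that class).
#' @param weight_floor lower bound on per-point weights relative to the mean
#'   (regularizes inverse-variance weights).
#' @return Object of class `rfree_fit`: list with `rfree`
#'   (an [rfree_trajectory()], degree-3 polynomial smoothing attached),
#'   `constants` (named list of [tir_constants()]), `residual_mse`, `gauge`,
#'   `objective_trace` (best start), `diagnostics` (per-start objectives,
#'   convergence flags, identifiability warning).
#' @export
joint_fit <- function(data, gauge = c("ref_ratio", "anchor_slowest"),
                      ref_id = NULL, n_starts = 20, seed = 1L,
                      scale = c("log", "linear"),
                      tol = 1e-10, max_iter = 500,
                      k2_max_factor = 1e4, weight_floor = 0.1) {
  gauge <- match.arg(gauge)
  scale <- match.arg(scale)
  prep <- .prepare_lambda_matrix(data, weight_floor)
  Y <- prep$Y; W <- prep$W; mu <- prep$mu
  ids <- rownames(Y); conds <- colnames(Y)
  n_id <- length(ids); n_c <- length(conds)
  if (is.null(ref_id)) ref_id <- ids[1]
  if (gauge == "ref_ratio" && !ref_id %in% ids)
    stop("ref_id '", ref_id, "' not among the fitted ids")
  obs_per_id <- rowSums(!is.na(Y))
  if (any(obs_per_id < 3))
    stop("every id must be observed in >= 3 conditions; offending: ",
         paste(ids[obs_per_id < 3], collapse = ", "))

  # R is searched on a fixed log-grid window around 1 (the gauge rescales
  # afterwards); K2 within [tiny, k2_max_factor * max R]
  lr_lo <- log(1e-4); lr_hi <- log(1e4)

  obj_terms <- if (scale == "log") {
    function(Yv, Wv, pred_log) Wv * (Yv - pred_log)^2
  } else {
    function(Yv, Wv, pred_log) Wv * (exp(Yv) - exp(pred_log))^2
  }

  fit_one_id <- function(y, w, logR) {
    ok <- !is.na(y)
    y <- y[ok]; w <- w[ok]; lr <- logR[ok]
    R <- exp(lr)
    sse_k2 <- function(lk2) {
      b <- lr - log(exp(lk2) + R)
      lk1 <- sum(w * (y - b)) / sum(w)
      sum(obj_terms(y, w, lk1 + b))
    }
    k2_hi <- log(k2_max_factor * max(R))
    opt <- stats::optimize(sse_k2, c(log(1e-8 * min(R)), k2_hi), tol = 1e-12)
    # saturated boundary: K2 -> 0 exactly
    b0 <- rep(0, length(y)); lk1_0 <- sum(w * y) / sum(w)
    sse0 <- sum(obj_terms(y, w, lk1_0 + b0))
    if (sse0 < opt$objective) {
      lk2 <- -Inf; sse <- sse0
    } else { lk2 <- opt$minimum; sse <- opt$objective }
    k2 <- exp(lk2)
    b <- lr - log(k2 + R)
    lk1 <- sum(w * (y - b)) / sum(w)
    c(k1 = exp(lk1), k2 = k2, sse = sse)
  }

  fit_one_cond <- function(yc, wc, k1, k2) {
    ok <- !is.na(yc)
    y <- yc[ok]; w <- wc[ok]; K1 <- k1[ok]; K2 <- k2[ok]
    f <- function(lr) {
      R <- exp(lr)
      sum(obj_terms(y, w, log(K1) + lr - log(K2 + R)))
    }
    stats::optimize(f, c(lr_lo, lr_hi), tol = 1e-12)$minimum
  }

  objective <- function(logR, k1, k2) {
    total <- 0
    for (i in seq_len(n_id)) {
      ok <- !is.na(Y[i, ])
      pred <- log(k1[i]) + logR[ok] - log(k2[i] + exp(logR[ok]))
      total <- total + sum(obj_terms(Y[i, ok], W[i, ok], pred))
    }
    total
  }

  run_start <- function(logR0) {
    logR <- logR0
    k1 <- rep(1, n_id); k2 <- rep(1, n_id)
    prev <- Inf; trace <- numeric(0); converged <- FALSE
    for (it in seq_len(max_iter)) {
      for (i in seq_len(n_id)) {
        f <- fit_one_id(Y[i, ], W[i, ], logR)
        k1[i] <- f[["k1"]]; k2[i] <- f[["k2"]]
      }
      for (cidx in seq_len(n_c)) {
        logR[cidx] <- fit_one_cond(Y[, cidx], W[, cidx], k1, k2)
      }
      cur <- objective(logR, k1, k2)
      trace <- c(trace, cur)
      if (is.finite(prev) && abs(prev - cur) <= tol * (1 + abs(prev))) {
        converged <- TRUE; break
      }
      prev <- cur
    }
    list(logR = logR, k1 = k1, k2 = k2, obj = cur, trace = trace,
         converged = converged)
  }

  # initializations: one data-driven start (per-condition mean log-lambda,
  # centred) plus seeded random starts
  set.seed(seed)
  ybar <- colMeans(Y, na.rm = TRUE)
  starts <- list(ybar - max(ybar))
  if (n_starts > 1) {
    for (s in seq_len(n_starts - 1)) {
      starts[[s + 1]] <- stats::rnorm(n_c, mean = 0, sd = 1)
    }
  }
  runs <- lapply(starts, run_start)
  objs <- vapply(runs, `[[`, numeric(1), "obj")
  # tie-break: lowest objective, then lowest K2 l2-norm
  best_obj <- min(objs)
  cand <- which(objs <= best_obj * (1 + 1e-9) + 1e-300)
  if (length(cand) > 1) {
    k2n <- vapply(runs[cand], function(r) sum(r$k2^2), numeric(1))
    best <- cand[which.min(k2n)]
  } else best <- cand
  fit <- runs[[best]]

  R <- exp(fit$logR); k1 <- fit$k1; k2 <- fit$k2
  # The model carries a second exact invariance besides the scale gauge:
  # with x = 1/R, alpha = 1/K1, beta = K2/K1, predictions depend only on
  # alpha_i + beta_i x_c, so x -> x + t with alpha -> alpha - beta t leaves
  # every lambda unchanged. We resolve it by convention: transform so the
  # largest fitted K2 sits exactly at k2_max_factor * max R (the finite cap
  # for undersaturated transcripts), which is exact and objective-invariant.
  if (any(k2 > 0)) {
    j <- which.max(k2)
    alpha_j <- 1 / k1[j]; beta_j <- k2[j] / k1[j]
    minx <- 1 / max(R)
    tstar <- (k2_max_factor * alpha_j - beta_j * minx) /
      (beta_j * (1 + k2_max_factor))
    denom <- 1 - k2 * tstar
    k1 <- k1 / denom
    k2 <- k2 / denom
    R <- R / (1 + tstar * R)
  }
  all_sat <- all(k2 < 1e-6 * min(R))
  if (gauge == "ref_ratio") {
    iref <- match(ref_id, ids)
    if (k2[iref] <= 0)
      warning("reference id fitted saturated (K2 = 0); scale not identified, ",
              "falling back to anchor_slowest gauge")
    cfac <- if (k2[iref] > 0) k1[iref] / k2[iref] else 1 / R[1]
  } else {
    cfac <- 1 / R[1]
  }
  R <- R * cfac; k2 <- k2 * cfac
  if (all_sat)
    warning("all ids fitted saturated; free-ribosome scale not identified")

  consts <- stats::setNames(vector("list", n_id), ids)
  for (i in seq_len(n_id)) consts[[i]] <- tir_constants(k1[i], k2[i])
  traj <- rfree_trajectory(R, prep$conditions,
                           gauge = if (gauge == "ref_ratio") "ref_ratio" else "anchor_slowest")
  traj <- smooth_rfree(traj)
  n_obs <- sum(!is.na(Y))
  structure(list(
    rfree = traj, constants = consts,
    residual_mse = fit$obj / n_obs, objective = fit$obj, gauge = gauge,
    objective_trace = fit$trace,
    diagnostics = list(start_objectives = objs,
                       start_dispersion = stats::sd(objs),
                       converged = fit$converged,
                       scale_identified = !all_sat,
                       n_iter = length(fit$trace))),
    class = "rfree_fit")
}

# shared input munging: long data -> per-(id, condition) weighted mean
# log-lambda matrix Y, weight matrix W (inverse replicate variance of log
# lambda times replicate count, floor-regularized), condition grid
.prepare_lambda_matrix <- function(data, weight_floor = 0.1) {
  data <- as.data.frame(data)
  if (!"lambda" %in% names(data)) {
    if (!all(c("P", "m") %in% names(data)))
      stop("data needs either a lambda column or P and m columns")
    if (any(data$m == 0)) stop("zero mRNA abundance: lambda undefined")
    data$lambda <- data$mu * data$P / data$m
  }
  if (!all(c("id", "condition", "mu") %in% names(data)))
    stop("data needs columns id, condition, mu")
  if (any(data$lambda <= 0)) stop("lambda observations must be > 0")
  cm <- unique(data[, c("condition", "mu")])
  if (anyDuplicated(cm$condition)) stop("inconsistent mu within a condition")
  cm <- cm[order(cm$mu), ]
  conditions <- growth_conditions(cm$condition, cm$mu)
  ids <- unique(data$id)
  Y <- matrix(NA_real_, length(ids), nrow(conditions),
              dimnames = list(ids, conditions$name))
  V <- Y; N <- Y
  ll <- log(data$lambda)
  key <- split(seq_len(nrow(data)), list(data$id, data$condition), drop = TRUE)
  for (k in names(key)) {
    rows <- key[[k]]
    i <- data$id[rows[1]]; cc <- data$condition[rows[1]]
    Y[i, cc] <- mean(ll[rows])
    N[i, cc] <- length(rows)
    V[i, cc] <- if (length(rows) > 1) stats::var(ll[rows]) else NA_real_
  }
  vbar <- mean(V, na.rm = TRUE)
  if (!is.finite(vbar) || vbar <= 0) {
    W <- N  # no replicate information: weight by replicate count
  } else {
    V[is.na(V)] <- vbar
    V <- pmax(V, weight_floor * vbar)
    W <- N / V
  }
  W[is.na(Y)] <- NA_real_
  list(Y = Y, W = W, mu = conditions$mu, conditions = conditions)
}

#' Classify a transcript by ribosome saturation
#'
#' Saturated when K2 is far below the spanned free-ribosome range
#' (`K2 < theta_low * min R`), undersaturated when far above
#' (`K2 > theta_high * max R`), unsaturated otherwise. Thresholds are
#' relative to the R range, so classification is gauge-invariant.
#'
#' @param consts a `tir_constants` object.
#' @param rfree an `rfree_trajectory` in the same gauge.
#' @param theta_low,theta_high class thresholds (defaults 0.1 and 10).
#' @return `"saturated"`, `"unsaturated"` or `"undersaturated"`.
#' @export
classify_transcript <- function(consts, rfree, theta_low = 0.1, theta_high = 10) {
  r <- rfree$values
  if (consts$k2 < theta_low * min(r)) "saturated"
  else if (consts$k2 > theta_high * max(r)) "undersaturated"
  else "unsaturated"
}

#' Genome-wide joint fit, classification and efficiency normalization
#'
#' Filters an omics panel to genes detected in at least `min_conditions`
#' conditions, computes per-condition efficiencies `lambda = mu * P / m`
#' from replicate-averaged abundances, runs [joint_fit()] (R anchored at the
#' slowest condition), classifies every gene, and reports the class table,
#' the K1-K2 correlation among unsaturated genes, normalized per-gene
#' efficiency profiles (anchored at the slowest condition) and a class-count
#' sensitivity sweep over the thresholds.
#'
#' @param panel an `omics_panel`.
#' @param min_conditions detection filter (default 3).
#' @param gauge gauge convention (default `"anchor_slowest"`).
#' @param seed RNG seed passed to [joint_fit()].
#' @param n_starts multistart count for the genome-scale fit (default 5).
#' @param theta_low,theta_high class thresholds.
#' @param ... further arguments to [joint_fit()].
#' @return List with `fit` (the `rfree_fit`), `class_table` (data frame:
#'   gene, class, k1, k2, k1_over_k2), `class_counts`, `excluded` (genes
#'   failing the filter), `correlation` (Pearson/Spearman of log K1 vs log
#'   K2 among unsaturated genes), `efficiency_profiles` (gene x condition,
#'   normalized to the slowest condition) and `threshold_sensitivity`.
#' @export
genome_wide_fit <- function(panel, min_conditions = 3,
                            gauge = "anchor_slowest", seed = 1L,
                            n_starts = 5, theta_low = 0.1, theta_high = 10,
                            ...) {
  stopifnot(inherits(panel, "omics_panel"))
  cond <- panel$conditions
  det <- panel$detected
  keep <- rownames(det)[rowSums(det) >= min_conditions]
  excluded <- setdiff(panel$genes, keep)
  if (!length(keep)) stop("no gene passes the detection filter")
  m_bar <- apply(panel$transcript, c(1, 2), mean)
  p_bar <- apply(panel$protein, c(1, 2), mean)
  p_var <- apply(log(pmax(panel$protein, .Machine$double.xmin)), c(1, 2),
                 stats::var)
  rows <- list()
  for (g in keep) {
    for (j in seq_len(nrow(cond))) {
      if (!det[g, j]) next
      rows[[length(rows) + 1L]] <- data.frame(
        id = g, condition = cond$name[j], mu = cond$mu[j],
        lambda = cond$mu[j] * p_bar[g, j] / m_bar[g, j],
        stringsAsFactors = FALSE)
    }
  }
  data <- do.call(rbind, rows)
  fit <- joint_fit(data, gauge = gauge, seed = seed, n_starts = n_starts, ...)
  classify_all <- function(tl, th) {
    vapply(fit$constants, classify_transcript, character(1),
           rfree = fit$rfree, theta_low = tl, theta_high = th)
  }
  classes <- classify_all(theta_low, theta_high)
  k1 <- vapply(fit$constants, `[[`, numeric(1), "k1")
  k2 <- vapply(fit$constants, `[[`, numeric(1), "k2")
  class_table <- data.frame(gene = names(classes), class = unname(classes),
                            k1 = unname(k1), k2 = unname(k2),
                            k1_over_k2 = unname(ifelse(k2 > 0, k1 / k2, Inf)),
                            stringsAsFactors = FALSE)
  class_counts <- table(factor(classes,
    levels = c("saturated", "unsaturated", "undersaturated")))
  uns <- class_table$class == "unsaturated"
  correlation <- if (sum(uns) >= 3) {
    lk1 <- log10(class_table$k1[uns]); lk2 <- log10(class_table$k2[uns])
    c(pearson = stats::cor(lk1, lk2, method = "pearson"),
      spearman = stats::cor(lk1, lk2, method = "spearman"))
  } else c(pearson = NA_real_, spearman = NA_real_)
  lam_hat <- t(vapply(fit$constants, function(cs)
    translation_efficiency(cs, fit$rfree$values), numeric(nrow(cond))))
  eff_norm <- lam_hat / lam_hat[, 1]
  dimnames(eff_norm) <- list(names(fit$constants), cond$name)
  sens <- expand.grid(theta_low = c(0.05, 0.1, 0.2),
                      theta_high = c(5, 10, 20))
  sens_counts <- t(apply(sens, 1, function(tt) {
    table(factor(classify_all(tt[1], tt[2]),
                 levels = c("saturated", "unsaturated", "undersaturated")))
  }))
  list(fit = fit, class_table = class_table, class_counts = class_counts,
       excluded = excluded, correlation = correlation,
       efficiency_profiles = eff_norm,
       threshold_sensitivity = cbind(sens, sens_counts))
}

#' Re-infer the free-ribosome trajectory under a perturbation
#'
#' With the per-transcript constants clamped at their unperturbed values,
#' each condition's R is a 1-D least-squares solve on the perturbed
#' efficiency observations; reports the fold-change against an unperturbed
#' trajectory when one is supplied.
#'
#' @param data perturbed observations in the [joint_fit()] input format.
#' @param constants named list of `tir_constants` fitted on unperturbed data.
#' @param unperturbed optional `rfree_trajectory` for fold-change reporting.
#' @param gauge gauge recorded on the result (the constants carry the scale,
#'   so the perturbed trajectory is directly comparable; no rescaling done).
#' @param weight_floor weight regularization as in [joint_fit()].
#' @return List with `rfree` (an `rfree_trajectory`), `fold_change`
#'   (perturbed / unperturbed per condition, if available), `flagged`
#'   (conditions absent from the unperturbed calibration).
#' @export
infer_perturbed_rfree <- function(data, constants, unperturbed = NULL,
                                  gauge = "ref_ratio", weight_floor = 0.1) {
  prep <- .prepare_lambda_matrix(data, weight_floor)
  Y <- prep$Y; W <- prep$W
  ids <- rownames(Y)
  missing_ids <- setdiff(ids, names(constants))
  if (length(missing_ids))
    stop("no fitted constants for id(s): ", paste(missing_ids, collapse = ", "))
  k1 <- vapply(constants[ids], `[[`, numeric(1), "k1")
  k2 <- vapply(constants[ids], `[[`, numeric(1), "k2")
  R <- numeric(ncol(Y))
  for (cidx in seq_len(ncol(Y))) {
    ok <- !is.na(Y[, cidx])
    y <- Y[ok, cidx]; w <- W[ok, cidx]
    K1 <- k1[ok]; K2 <- k2[ok]
    f <- function(lr) {
      Rv <- exp(lr)
      sum(w * (y - (log(K1) + lr - log(K2 + Rv)))^2)
    }
    R[cidx] <- exp(stats::optimize(f, c(log(1e-6), log(1e6)), tol = 1e-12)$minimum)
  }
  traj <- rfree_trajectory(R, prep$conditions, gauge = gauge)
  fold <- NULL; flagged <- character(0)
  if (!is.null(unperturbed)) {
    common <- intersect(prep$conditions$name, names(unperturbed$values))
    flagged <- setdiff(prep$conditions$name, common)
    fold <- traj$values[common] / unperturbed$values[common]
  }
  list(rfree = traj, fold_change = fold, flagged = flagged)
}

#' Over-representation of a gene set across saturation classes
#'
#' One-sided hypergeometric over-representation test of a marked gene set
#' (e.g. long-5'UTR messengers) within each saturation class of a class
#' table.
#'
#' @param class_table data frame with columns `gene`, `class` (as from
#'   [genome_wide_fit()]).
#' @param marked_ids character vector of marked genes; ids outside the
#'   classified universe are reported and ignored.
#' @return Data frame (class, class_size, overlap, p_value) with one-sided
#'   (over-representation) hypergeometric p-values.
#' @export
long_utr_enrichment <- function(class_table, marked_ids) {
  universe <- class_table$gene
  unknown <- setdiff(marked_ids, universe)
  if (length(unknown))
    warning(length(unknown), " marked id(s) not in the classified universe; ignored")
  marked <- intersect(marked_ids, universe)
  if (!length(marked)) {
    warning("empty marked set: all p-values are 1")
  }
  classes <- c("saturated", "unsaturated", "undersaturated")
  rows <- lapply(classes, function(cl) {
    in_class <- class_table$gene[class_table$class == cl]
    k <- length(intersect(marked, in_class))
    p <- if (length(marked) == 0) 1 else
      stats::phyper(k - 1, length(marked), length(universe) - length(marked),
                    length(in_class), lower.tail = FALSE)
    data.frame(class = cl, class_size = length(in_class), overlap = k,
               p_value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
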