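#' Polynomial trend fit with bootstrap confidence band
#'
#' Ordinary least-squares polynomial fit of replicate observations against
#' growth rate, with a percentile bootstrap 95% band obtained by resampling
#' observations within each distinct x (preserving the design).
#'
#' @param x numeric predictor (growth rate), one per observation.
#' @param y numeric observations (replicates share their x value).
#' @param degree polynomial degree; requires more distinct x than `degree`.
#' @param B bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @param x_out evaluation grid (default the distinct x values).
#' @return List with `coefficients` (intercept first), `fitted`, `lower`,
#'   `upper` on `x_out`, `x_out`, and `predict` (a function of x).
#' @export
fit_trend <- function(x, y, degree, B = 1000, seed = 1L, x_out = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ux <- sort(unique(x))
  if (length(ux) <= degree)
    stop(sprintf("degenerate design: %d distinct x for degree %d (need > degree)",
                 length(ux), degree))
  if (is.null(x_out)) x_out <- ux
  X <- stats::poly(x, degree = degree, raw = TRUE)
  fit <- stats::lm(y ~ X)
  coefs <- unname(stats::coef(fit))
  pred <- function(xx) {
    drop(cbind(1, stats::poly(xx, degree = degree, raw = TRUE)) %*% coefs)
  }
  lower <- upper <- rep(NA_real_, length(x_out))
  if (B > 0) {
    set.seed(seed)
    idx_by_x <- split(seq_along(x), x)
    Xout <- cbind(1, stats::poly(x_out, degree = degree, raw = TRUE))
    boot <- matrix(NA_real_, nrow = B, ncol = length(x_out))
    Xfull <- cbind(1, X)
    for (b in seq_len(B)) {
      take <- unlist(lapply(idx_by_x, function(ii)
        ii[sample.int(length(ii), length(ii), replace = TRUE)]),
        use.names = FALSE)
      cb <- stats::lm.fit(Xfull[take, , drop = FALSE], y[take])$coefficients
      cb[is.na(cb)] <- 0
      boot[b, ] <- drop(Xout %*% cb)
    }
    qs <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
    lower <- qs[1, ]; upper <- qs[2, ]
  }
  list(coefficients = coefs, fitted = pred(x_out), lower = lower,
       upper = upper, x_out = x_out, predict = pred)
}

#' Transcript-stability correction from qPCR ratios
#'
#' Fits the reporter/reference mRNA ratio against growth rate with a
#' third-order polynomial (the stability curve) and returns the correction:
#' corrected reporter mRNA = reference transcript abundance x fitted ratio.
#'
#' @param qpcr data frame (condition, mu, replicate, ratio) for one strain.
#' @param degree polynomial degree (default 3; needs >= degree+1 distinct mu).
#' @param B,seed bootstrap settings passed to [fit_trend()].
#' @return List with `ratio_fun` (function of mu), `fit` (the [fit_trend()]
#'   result) and `correct` (function(reference_abundance, mu) -> corrected
#'   reporter mRNA).
#' @export
stability_correction <- function(qpcr, degree = 3, B = 1000, seed = 1L) {
  need <- c("mu", "ratio")
  if (!all(need %in% names(qpcr))) stop("qpcr needs columns mu and ratio")
  if (any(qpcr$ratio <= 0)) stop("nonpositive qPCR ratio in input")
  fit <- fit_trend(qpcr$mu, qpcr$ratio, degree = degree, B = B, seed = seed)
  ratio_fun <- fit$predict
  list(ratio_fun = ratio_fun, fit = fit,
       correct = function(reference_abundance, mu) reference_abundance * ratio_fun(mu))
}

#' Translation-efficiency profile of a reporter strain
#'
#' Computes `lambda_c = mu_c * mean(P_c) / m_c` per condition from replicate
#' fluorescence abundances and the (stability-corrected) reporter mRNA
#' abundance, with a replicate-bootstrap 95% CI.
#'
#' @param fluor data frame (condition, mu, replicate, value) for one strain.
#' @param mrna data frame (condition, abundance): corrected reporter mRNA.
#' @param B,seed bootstrap settings.
#' @return Data frame (condition, mu, lambda, lower, upper, n_replicates).
#' @export
efficiency_profile <- function(fluor, mrna, B = 1000, seed = 1L) {
  if (!all(c("condition", "mu", "value") %in% names(fluor)))
    stop("fluor needs columns condition, mu, value")
  m <- stats::setNames(mrna$abundance, mrna$condition)
  conds <- unique(fluor$condition)
  if (!all(conds %in% names(m)))
    stop("mRNA abundance missing for condition(s): ",
         paste(setdiff(conds, names(m)), collapse = ", "))
  if (any(m[conds] == 0)) stop("zero mRNA abundance: efficiency undefined")
  set.seed(seed)
  rows <- lapply(conds, function(cc) {
    d <- fluor[fluor$condition == cc, ]
    lam <- d$mu[1] * mean(d$value) / m[[cc]]
    if (B > 0 && nrow(d) > 1) {
      bb <- vapply(seq_len(B), function(b) {
        d$mu[1] * mean(sample(d$value, nrow(d), replace = TRUE)) / m[[cc]]
      }, numeric(1))
      ci <- stats::quantile(bb, c(0.025, 0.975))
    } else ci <- c(lam, lam)
    data.frame(condition = cc, mu = d$mu[1], lambda = lam,
               lower = unname(ci[1]), upper = unname(ci[2]),
               n_replicates = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$mu), , drop = FALSE]
}

#' Translation-efficiency ratio between two reporter strains
#'
#' Per-condition mean-square-error ratio estimate: the protein-abundance
#' ratio `r = argmin_r sum over all replicate pairs (P_a - r P_b)^2 =
#' sum(P_a P_b) / sum(P_b^2)` (all-vs-all pairing within the condition),
#' converted to an efficiency ratio by the corrected mRNA abundances
#' (`lambda_a / lambda_b = r * m_b / m_a`), with a percentile bootstrap CI
#' over replicates.
#'
#' @param fluor_a,fluor_b replicate fluorescence tables (condition, mu,
#'   value) for strains a and b over the same conditions.
#' @param mrna_a,mrna_b corrected mRNA tables (condition, abundance); when
#'   omitted the raw protein ratio is returned.
#' @param B,seed bootstrap settings.
#' @return Data frame (condition, mu, ratio, lower, upper).
#' @export
efficiency_ratio <- function(fluor_a, fluor_b, mrna_a = NULL, mrna_b = NULL,
                             B = 1000, seed = 1L) {
  ca <- sort(unique(fluor_a$condition)); cb <- sort(unique(fluor_b$condition))
  if (!identical(ca, cb))
    stop("condition sets differ: ",
         paste(union(setdiff(ca, cb), setdiff(cb, ca)), collapse = ", "))
  mfac <- stats::setNames(rep(1, length(ca)), ca)
  if (!is.null(mrna_a) && !is.null(mrna_b)) {
    ma <- stats::setNames(mrna_a$abundance, mrna_a$condition)
    mb <- stats::setNames(mrna_b$abundance, mrna_b$condition)
    mfac <- mb[ca] / ma[ca]
  }
  lsq_ratio <- function(pa, pb) {
    # all-vs-all pairs: sum_{ij} pa_i pb_j / sum_{ij} pb_j^2
    (sum(pa) * sum(pb)) / (length(pa) * sum(pb^2))
  }
  set.seed(seed)
  rows <- lapply(ca, function(cc) {
    pa <- fluor_a$value[fluor_a$condition == cc]
    pb <- fluor_b$value[fluor_b$condition == cc]
    mu <- fluor_a$mu[fluor_a$condition == cc][1]
    est <- lsq_ratio(pa, pb) * mfac[[cc]]
    if (B > 0) {
      bb <- vapply(seq_len(B), function(b) {
        lsq_ratio(sample(pa, length(pa), replace = TRUE),
                  sample(pb, length(pb), replace = TRUE)) * mfac[[cc]]
      }, numeric(1))
      ci <- stats::quantile(bb, c(0.025, 0.975))
    } else ci <- c(est, est)
    data.frame(condition = cc, mu = mu, ratio = est,
               lower = unname(ci[1]), upper = unname(ci[2]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$mu), , drop = FALSE]
}
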