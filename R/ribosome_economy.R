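#' Transcript pool for the ribosome-conservation relation
#'
#' Per-gene mRNA abundances with their translation constants and elongation
#' parameters: the inputs of the whole-proteome conservation relation
#' linking total ribosomes, the transcript pool and free ribosomes.
#'
#' @param m named numeric vector of mRNA abundances (>= 0).
#' @param constants named list of `tir_constants` matching `m`.
#' @param kp elongation completion rates, h^-1 (scalar or per gene; > 0).
#' @return An object of class `transcript_pool`.
#' @export
transcript_pool <- function(m, constants, kp = 1) {
  if (is.null(names(m)) && length(m)) names(m) <- sprintf("g%03d", seq_along(m))
  cn <- names(constants); if (is.null(cn)) cn <- character(0)
  nm <- names(m); if (is.null(nm)) nm <- character(0)
  if (!identical(sort(nm), sort(cn)))
    stop("m and constants must cover the same genes")
  if (any(m < 0)) stop("mRNA abundances must be >= 0")
  kp <- rep_len(kp, length(m)); names(kp) <- names(m)
  if (any(kp <= 0)) stop("kp must be > 0")
  structure(list(m = m, constants = constants[names(m)], kp = kp),
            class = "transcript_pool")
}

#' Ribosomes sequestered by each transcript
#'
#' Translating ribosomes in transit on transcript i: initiation flux times
#' the mean elongation time, `bound_i = m_i * lambda_i(R) / kp_i`. With
#' `include_occupancy = TRUE` the 30S complexes held in the initiation
#' intermediates are added via the three-step reduction (off by default; the
#' default reading counts only elongating ribosomes). Each term is
#' nondecreasing in R.
#'
#' @param pool a `transcript_pool`.
#' @param rfree free-ribosome abundance (>= 0).
#' @param include_occupancy include initiation-complex occupancy (default
#'   FALSE; requires `occupancy` rates attached to the pool as attribute
#'   `occupancy_fraction`, a per-gene multiplier on `m_i * R/(K2_i + R)`).
#' @return Named numeric vector of sequestered ribosomes per gene.
#' @export
bound_ribosomes <- function(pool, rfree, include_occupancy = FALSE) {
  stopifnot(inherits(pool, "transcript_pool"))
  if (rfree < 0) stop("rfree must be >= 0")
  lam <- vapply(pool$constants, function(cs) {
    if (cs$k2 == 0 && rfree == 0) 0 else translation_efficiency(cs, rfree)
  }, numeric(1))
  bound <- pool$m * lam / pool$kp
  if (include_occupancy) {
    occ <- attr(pool, "occupancy_fraction")
    if (is.null(occ)) occ <- 0
    k2 <- vapply(pool$constants, `[[`, numeric(1), "k2")
    bound <- bound + occ * pool$m * rfree / (k2 + rfree + (k2 + rfree == 0))
  }
  bound
}

#' Solve the ribosome-conservation fixed point for the free pool
#'
#' Finds the unique root of `f(R) = R + sum_i bound_i(R) - r_tot` on
#' `[0, r_tot]` by bracketed bisection. `f` is strictly increasing
#' (`f(0) = -r_tot < 0`, `f(r_tot) >= 0`), so the root exists and is unique;
#' bisection runs to `|f| < 1e-12 * r_tot`.
#'
#' @param r_tot total ribosome abundance (> 0).
#' @param pool a `transcript_pool`.
#' @param tol conservation tolerance relative to `r_tot`.
#' @param include_occupancy passed to [bound_ribosomes()].
#' @return List of class `ribosome_pool`: `r_tot`, `r_free`,
#'   `bound_per_gene`, `residual` (conservation residual).
#' @export
solve_rfree <- function(r_tot, pool, tol = 1e-12, include_occupancy = FALSE) {
  if (r_tot <= 0) stop("r_tot must be > 0")
  f <- function(R) R + sum(bound_ribosomes(pool, R, include_occupancy)) - r_tot
  lo <- 0; hi <- r_tot
  flo <- f(lo); fhi <- f(hi)
  if (flo >= 0) {  # empty/ineffective pool edge: root at 0 impossible, flo = -r_tot
    stop("conservation function does not bracket a root")  # unreachable for valid input
  }
  repeat {
    mid <- 0.5 * (lo + hi)
    fm <- f(mid)
    if (abs(fm) < tol * r_tot || (hi - lo) < .Machine$double.eps * r_tot) break
    if (fm < 0) lo <- mid else hi <- mid
  }
  bound <- bound_ribosomes(pool, mid, include_occupancy)
  structure(list(r_tot = r_tot, r_free = mid, bound_per_gene = bound,
                 residual = mid + sum(bound) - r_tot),
            class = "ribosome_pool")
}

# secondary solver: damped fixed-point iteration R <- R + a (r_tot - R - sum bound)
# used as an independent cross-check of the bisection root
solve_rfree_fixed_point <- function(r_tot, pool, damping = 0.5,
                                    tol = 1e-12, max_iter = 100000) {
  R <- r_tot / 2
  for (i in seq_len(max_iter)) {
    g <- r_tot - R - sum(bound_ribosomes(pool, R))
    R_new <- min(max(R + damping * g, 0), r_tot)
    if (abs(g) < tol * r_tot) return(R_new)
    R <- R_new
  }
  R
}

#' Equilibrium shift across growth scenarios
#'
#' Solves the conservation fixed point for a list of (r_tot, pool)
#' scenarios and reports whether the free pool drops despite the total pool
#' growing, labelling the driving mechanism: an overall mRNA-mass increase
#' (stronger titration by more message) and/or a reorganization of the pool
#' toward low-K2 (avidly initiating) transcripts.
#'
#' @param scenarios list of lists with elements `r_tot` and `pool`.
#' @return List with `trajectory` (data frame r_tot, r_free, mrna_mass,
#'   low_k2_share) and `report` (per-transition mechanism labels and flags).
#' @export
equilibrium_shift <- function(scenarios) {
  if (length(scenarios) < 2) stop("need at least 2 scenarios")
  solved <- lapply(scenarios, function(sc) solve_rfree(sc$r_tot, sc$pool))
  stat <- function(sc) {
    k2 <- vapply(sc$pool$constants, `[[`, numeric(1), "k2")
    mass <- sum(sc$pool$m)
    med <- stats::median(k2)
    low_share <- sum(sc$pool$m[k2 <= med]) / mass
    c(mass = mass, low_k2_share = low_share)
  }
  stats_tab <- t(vapply(scenarios, stat, numeric(2)))
  traj <- data.frame(
    r_tot = vapply(solved, `[[`, numeric(1), "r_tot"),
    r_free = vapply(solved, `[[`, numeric(1), "r_free"),
    mrna_mass = stats_tab[, "mass"],
    low_k2_share = stats_tab[, "low_k2_share"])
  report <- lapply(seq_len(nrow(traj) - 1), function(i) {
    mech <- character(0)
    if (traj$mrna_mass[i + 1] > traj$mrna_mass[i] * (1 + 1e-12))
      mech <- c(mech, "mrna_mass_increase")
    if (traj$low_k2_share[i + 1] > traj$low_k2_share[i] + 1e-12)
      mech <- c(mech, "low_k2_reorganization")
    list(from = i, to = i + 1,
         r_tot_increased = traj$r_tot[i + 1] > traj$r_tot[i],
         r_free_decreased = traj$r_free[i + 1] < traj$r_free[i],
         mechanisms = mech)
  })
  list(trajectory = traj, report = report)
}

#' Ribosomal-mRNA enrichment scenario
#'
#' Asks whether enriching only the ribosomal mRNAs (their reported
#' fast-growth behaviour) while the total ribosome pool grows can by itself
#' reproduce a target drop in free-ribosome abundance: builds the
#' fast-growth pool by multiplying the ribosomal transcripts by
#' `enrichment`, scales `r_tot` by `r_tot_growth`, solves both conditions
#' and reports the fold-change with an `insufficient_alone` flag when the
#' target is not met.
#'
#' @param base a `transcript_pool` for the slow-growth condition.
#' @param ribosomal_ids genes treated as ribosomal transcripts (near-zero
#'   K2 expected; nonempty).
#' @param r_tot total ribosomes at slow growth.
#' @param enrichment ribosomal-mRNA fold increase (default 2.5).
#' @param r_tot_growth total-ribosome fold increase (default 2).
#' @param target_drop free-ribosome fold drop the scenario is tested
#'   against (default 4).
#' @return List with `r_free_slow`, `r_free_fast`, `fold_drop`,
#'   `target_drop`, `insufficient_alone`, and `ribosomal_bound_offset` (the
#'   R-independent titration offset the saturated ribosomal genes add).
#' @export
ribosomal_feedback_scenario <- function(base, ribosomal_ids, r_tot,
                                        enrichment = 2.5, r_tot_growth = 2,
                                        target_drop = 4) {
  stopifnot(inherits(base, "transcript_pool"))
  if (!length(ribosomal_ids)) stop("ribosomal_ids must be nonempty")
  if (!all(ribosomal_ids %in% names(base$m)))
    stop("unknown ribosomal id(s): ",
         paste(setdiff(ribosomal_ids, names(base$m)), collapse = ", "))
  m_fast <- base$m
  m_fast[ribosomal_ids] <- m_fast[ribosomal_ids] * enrichment
  fast <- transcript_pool(m_fast, base$constants, base$kp)
  slow_sol <- solve_rfree(r_tot, base)
  fast_sol <- solve_rfree(r_tot * r_tot_growth, fast)
  fold_drop <- slow_sol$r_free / fast_sol$r_free
  k1 <- vapply(base$constants, `[[`, numeric(1), "k1")
  offset <- sum(m_fast[ribosomal_ids] * k1[ribosomal_ids] /
                  base$kp[ribosomal_ids])
  list(r_free_slow = slow_sol$r_free, r_free_fast = fast_sol$r_free,
       fold_drop = fold_drop, target_drop = target_drop,
       insufficient_alone = fold_drop < target_drop,
       ribosomal_bound_offset = offset)
}
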