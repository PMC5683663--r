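#' Per-transcript translation-efficiency constants
#'
#' The two aggregated, growth rate-independent constants of the
#' Michaelis-Menten translation-efficiency law
#' \eqn{\lambda = K_1 R_{free} / (K_2 + R_{free})}: `k1` (h^-1, the saturated
#' efficiency) and `k2` (in free-ribosome units, the half-saturation point).
#' `sat_class` optionally records the saturation class of the transcript
#' relative to the free-ribosome range.
#'
#' @param k1,k2 nonnegative scalars.
#' @param sat_class `"saturated"`, `"unsaturated"`, `"undersaturated"` or `NA`.
#' @return An object of class `tir_constants`.
#' @export
tir_constants <- function(k1, k2, sat_class = NA_character_) {
  stopifnot(is.numeric(k1), is.numeric(k2), length(k1) == 1, length(k2) == 1)
  if (!is.finite(k1) || !is.finite(k2) || k1 < 0 || k2 < 0)
    stop("k1 and k2 must be finite and >= 0")
  if (!is.na(sat_class))
    sat_class <- match.arg(sat_class, c("saturated", "unsaturated", "undersaturated"))
  structure(list(k1 = k1, k2 = k2, sat_class = sat_class), class = "tir_constants")
}

#' Michaelis-Menten translation efficiency
#'
#' Evaluates \eqn{\lambda = K_1 R / (K_2 + R)}: the number of proteins
#' produced per mRNA per hour as a function of the free-ribosome abundance R.
#' For `k2 = 0` the transcript is saturated and \eqn{\lambda = K_1} whenever
#' `R > 0`; `k2 = 0` together with `R = 0` is undefined.
#'
#' @param consts a `tir_constants` object (or list with `k1`, `k2`).
#' @param rfree nonnegative free-ribosome abundance (vectorized).
#' @return Translation efficiency in h^-1, same length as `rfree`.
#' @examples
#' translation_efficiency(tir_constants(1, 0.3), 0.7)  # 0.7
#' @export
translation_efficiency <- function(consts, rfree) {
  if (any(!is.finite(rfree)) || any(rfree < 0)) stop("rfree must be finite and >= 0")
  k1 <- consts$k1; k2 <- consts$k2
  if (k2 == 0 && any(rfree == 0))
    stop("translation efficiency undefined for K2 = 0 and R = 0")
  ifelse(rfree == 0 & k1 == 0, 0, k1 * rfree / (k2 + rfree))
}

#' Steady-state protein abundance
#'
#' At balanced growth a stable protein accumulates to
#' \eqn{P = m \lambda / (\mu + \gamma)}: synthesis flux `m * lambda` balanced
#' by dilution at rate mu and (optional) degradation at rate gamma.
#'
#' @param m transcript abundance (AU).
#' @param lam translation efficiency, h^-1.
#' @param mu growth rate, h^-1 (> 0).
#' @param gamma protein degradation rate, h^-1 (default 0: stable protein).
#' @return Protein abundance in `m * lam / (mu + gamma)` units.
#' @examples
#' protein_abundance(2, 2, 0.4)  # 10
#' @export
protein_abundance <- function(m, lam, mu, gamma = 0) {
  if (any(mu <= 0)) stop("mu must be > 0")
  if (any(gamma < 0)) stop("gamma must be >= 0")
  if (any(mu + gamma == 0)) stop("mu + gamma must be > 0")
  m * lam / (mu + gamma)
}

#' Kinetic parameters of the three-step initiation scheme
#'
#' Primary constants of the mechanistic translation model: reversible binding
#' of the free 30S initiation complex to the mRNA (`kb`, `k_minus_b`),
#' reversible accommodation onto the start codon (`ka`, `k_minus_a`),
#' irreversible 50S joining that initiates elongation (`kt`), first-order
#' completion of elongation (`kp`, the population-averaged inverse elongation
#' time) and protein degradation (`gamma`).
#'
#' @param kb,k_minus_b,ka,k_minus_a,kt,kp,gamma nonnegative rates; `kp > 0`.
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(kb, k_minus_b, ka, k_minus_a, kt, kp, gamma = 0) {
  vals <- c(kb = kb, k_minus_b = k_minus_b, ka = ka, k_minus_a = k_minus_a,
            kt = kt, kp = kp, gamma = gamma)
  if (any(!is.finite(vals)) || any(vals < 0)) stop("all rates must be finite and >= 0")
  if (kp <= 0) stop("kp must be > 0")
  structure(as.list(vals), class = "kinetic_params")
}

#' Simulate the three-step initiation model to steady state
#'
#' Integrates the mass-action ODE system for one transcript with the free
#' 30S complex (`rfree`) and free 50S subunit (`s50`) clamped as boundary
#' species. States: `rb` (mRNA-bound 30S), `ra` (start-codon-accommodated)
#' and `rt` (elongating pool); free mRNA is `m_total - rb - ra` by
#' conservation. The protein synthesis flux is `kp * rt`.
#'
#' @param params a `kinetic_params` object.
#' @param rfree,s50 clamped abundances (>= 0).
#' @param m_total transcript copies (>= 0).
#' @param horizon integration horizon; steady state must be reached within it.
#' @param ss_tol steady-state criterion: max relative time-derivative.
#' @return List with `state` (rb, ra, rt, m_free, s50_free), `flux`
#'   (protein synthesis rate), `time` at detection, and `converged`.
#' @export
simulate_three_step <- function(params, rfree, s50, m_total,
                                horizon = 1e4, ss_tol = 1e-10) {
  stopifnot(inherits(params, "kinetic_params"))
  if (rfree < 0 || s50 < 0 || m_total < 0) stop("abundances must be >= 0")
  p <- params
  deriv <- function(t, y, parms) {
    mf <- m_total - y[["rb"]] - y[["ra"]]
    d_rb <- p$kb * rfree * mf - (p$k_minus_b + p$ka) * y[["rb"]] +
      p$k_minus_a * y[["ra"]]
    d_ra <- p$ka * y[["rb"]] - (p$k_minus_a + p$kt * s50) * y[["ra"]]
    d_rt <- p$kt * s50 * y[["ra"]] - p$kp * y[["rt"]]
    list(c(d_rb, d_ra, d_rt))
  }
  y0 <- c(rb = 0, ra = 0, rt = 0)
  if (m_total == 0) {
    return(list(state = c(rb = 0, ra = 0, rt = 0, m_free = 0, s50_free = s50),
                flux = 0, time = 0, converged = TRUE))
  }
  t_now <- 0; y <- y0; chunk <- max(1, horizon / 100)
  converged <- FALSE
  while (t_now < horizon) {
    t_end <- min(horizon, t_now + chunk)
    sol <- deSolve::ode(y = y, times = c(t_now, t_end), func = deriv,
                        parms = NULL, method = "lsoda",
                        rtol = 1e-12, atol = 1e-14)
    y <- sol[nrow(sol), c("rb", "ra", "rt")]
    if (any(y < -1e-9)) stop("integration failure: negative state")
    y <- pmax(y, 0)
    t_now <- t_end
    dy <- unlist(deriv(t_now, y, NULL))
    scale <- pmax(abs(y), 1e-12 * m_total, .Machine$double.xmin)
    if (max(abs(dy) / scale) < ss_tol) { converged <- TRUE; break }
  }
  if (!converged) {
    dy <- unlist(deriv(t_now, y, NULL))
    stop(sprintf(
      "three-step model did not reach steady state within horizon %g (max |dy|/|y| = %.3e)",
      horizon, max(abs(dy) / pmax(abs(y), 1e-12 * m_total))))
  }
  state <- c(rb = unname(y[["rb"]]), ra = unname(y[["ra"]]), rt = unname(y[["rt"]]),
             m_free = m_total - unname(y[["rb"]]) - unname(y[["ra"]]),
             s50_free = s50)
  list(state = state, flux = p$kp * unname(y[["rt"]]), time = t_now,
       converged = TRUE)
}

#' Reduce the three-step scheme to Michaelis-Menten constants
#'
#' Exact steady-state (quasi-steady-state) reduction of the three-step
#' initiation scheme with clamped free 30S and 50S pools. Solving the
#' stationarity conditions of the bound complexes under mRNA conservation
#' gives a per-mRNA synthesis flux of Michaelis-Menten form
#' \eqn{\lambda(R) = K_1 R / (K_2 + R)} with
#' \deqn{K_1 = \frac{k_t S\, k_a}{k_{-a} + k_t S + k_a}, \qquad
#'       K_2 = \frac{k_{-b}(k_{-a} + k_t S) + k_a k_t S}{k_b (k_{-a} + k_t S + k_a)}.}
#' The reduction is exact at steady state (the scheme is linear in the bound
#' complexes once R and S are clamped); it is validated against the ODE
#' integrator in the test suite.
#'
#' @param params a `kinetic_params` object.
#' @param s50 clamped free 50S abundance (> 0).
#' @return A `tir_constants` object.
#' @export
reduce_to_mm <- function(params, s50) {
  stopifnot(inherits(params, "kinetic_params"))
  if (s50 <= 0) stop("s50 must be > 0")
  kts <- params$kt * s50
  if (kts == 0) stop("non-productive scheme: kt * s50 = 0, no elongation exit")
  if (params$ka == 0) stop("non-productive scheme: ka = 0, no accommodation")
  if (params$kb == 0) stop("non-productive scheme: kb = 0, no binding")
  denom <- params$k_minus_a + kts + params$ka
  k1 <- kts * params$ka / denom
  k2 <- (params$k_minus_b * (params$k_minus_a + kts) + params$ka * kts) /
    (params$kb * denom)
  tir_constants(k1, k2)
}
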