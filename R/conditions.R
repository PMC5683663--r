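#' Growth condition set
#'
#' A growth condition is a medium label paired with the balanced growth rate
#' it supports. Condition sets are plain data frames with columns `name` and
#' `mu` (h^-1), sorted by increasing `mu`; they are the x-axis of every
#' trajectory in the package.
#'
#' @param name character vector of medium labels (unique).
#' @param mu numeric vector of growth rates in h^-1 (strictly positive).
#' @return A `data.frame` of class `growth_conditions` with columns `name`,
#'   `mu`, sorted by `mu`.
#' @examples
#' growth_conditions(c("slow", "fast"), c(0.4, 1.7))
#' @export
growth_conditions <- function(name, mu) {
  if (length(name) != length(mu)) stop("name and mu must have equal length")
  if (anyDuplicated(name)) stop("condition names must be unique")
  mu <- as.numeric(mu)
  if (any(!is.finite(mu)) || any(mu <= 0)) stop("all growth rates must be finite and > 0")
  ord <- order(mu)
  out <- data.frame(name = as.character(name)[ord], mu = mu[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("growth_conditions", "data.frame")
  out
}

#' Default eight-condition growth-rate grid
#'
#' The eight media and growth rates of the study design, from M9 pyruvate
#' (0.25 h^-1) to CHG (1.70 h^-1).
#'
#' @return A `growth_conditions` data frame with 8 rows.
#' @examples
#' default_conditions()
#' @export
default_conditions <- function() {
  growth_conditions(
    name = c("M9P", "M9SE", "S", "M9G", "M9M", "TS", "CH", "CHG"),
    mu   = c(0.25, 0.40, 0.60, 0.75, 0.80, 0.90, 1.20, 1.70)
  )
}

#' Free-ribosome trajectory
#'
#' Normalized free-ribosome (30S initiation complex) abundance evaluated on a
#' condition grid, together with the gauge convention that fixes its scale.
#' The model is identifiable only up to the joint rescaling
#' (R, K2) -> (cR, cK2), so every trajectory records which convention was
#' used: `"anchor_slowest"` (R at the slowest condition = 1) or `"ref_ratio"`
#' (K1/K2 of a reference construct = 1).
#'
#' @param values positive numeric vector, one entry per condition (named by
#'   condition when possible).
#' @param conditions a `growth_conditions` set matching `values`.
#' @param gauge one of `"anchor_slowest"`, `"ref_ratio"`.
#' @param poly_coeffs optional coefficients of a third-order polynomial
#'   smoothing of R over mu (intercept first).
#' @return An object of class `rfree_trajectory`.
#' @export
rfree_trajectory <- function(values, conditions, gauge = c("anchor_slowest", "ref_ratio"),
                             poly_coeffs = NULL) {
  gauge <- match.arg(gauge)
  values <- as.numeric(values)
  if (length(values) != nrow(conditions))
    stop("values must have one entry per condition")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("free-ribosome abundances must be finite and > 0")
  names(values) <- conditions$name
  structure(list(values = values, conditions = conditions, gauge = gauge,
                 poly_coeffs = poly_coeffs),
            class = "rfree_trajectory")
}

#' @export
print.rfree_trajectory <- function(x, ...) {
  cat("Free-ribosome trajectory (gauge: ", x$gauge, ")\n", sep = "")
  print(data.frame(condition = x$conditions$name, mu = x$conditions$mu,
                   rfree = unname(x$values)))
  invisible(x)
}

#' Smooth a free-ribosome trajectory over growth rate
#'
#' Fits a degree-3 polynomial to R(mu) (the convention used to display
#' inferred trajectories) and returns the coefficients plus an interpolator.
#'
#' @param traj an `rfree_trajectory`.
#' @return The trajectory with `poly_coeffs` filled in and an attribute
#'   `interp`, a monotone-safe function of mu.
#' @export
smooth_rfree <- function(traj) {
  mu <- traj$conditions$mu
  fit <- stats::lm(traj$values ~ stats::poly(mu, degree = 3, raw = TRUE))
  traj$poly_coeffs <- unname(stats::coef(fit))
  # hyman preserves monotone shape; fall back to a natural spline when the
  # fitted values are not monotone (noisy inferred trajectories)
  method <- if (!is.unsorted(rev(traj$values)) || !is.unsorted(traj$values))
    "hyman" else "natural"
  attr(traj, "interp") <- stats::splinefun(mu, traj$values, method = method)
  traj
}
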