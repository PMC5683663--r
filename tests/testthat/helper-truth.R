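# small fixture builders shared across test files

# reporter-library truth at given noise; defaults mirror the study conditions
make_truth <- function(noise_cv = 0.05, seed = 1L, ...) {
  generator_truth(noise_cv = noise_cv, seed = seed, ...)
}

# long-format joint-fit input from a generated reporter library
reporter_fit_data <- function(truth) {
  lib <- generate_reporter_library(truth)
  d <- data.frame(id = lib$fluorescence$strain,
                  condition = lib$fluorescence$condition,
                  mu = lib$fluorescence$mu,
                  P = lib$fluorescence$value,
                  stringsAsFactors = FALSE)
  d$m <- truth$transcript_truth[[1]][d$condition]
  d
}

# random valid kinetic parameter set (log-uniform rates)
random_kinetics <- function() {
  r <- function(lo, hi) exp(stats::runif(1, log(lo), log(hi)))
  kinetic_params(kb = r(0.5, 50), k_minus_b = r(0.1, 10),
                 ka = r(0.5, 50), k_minus_a = r(0.1, 10),
                 kt = r(1, 50), kp = r(0.5, 10))
}

# random transcript pool for the economy solver
random_pool <- function(n = 8) {
  m <- stats::runif(n, 0.1, 2)
  names(m) <- sprintf("g%02d", seq_len(n))
  consts <- lapply(seq_len(n), function(i)
    tir_constants(stats::runif(1, 0.5, 5), stats::runif(1, 0.05, 5)))
  names(consts) <- names(m)
  transcript_pool(m, consts, kp = stats::runif(n, 1, 20))
}
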