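test_that("polynomial trend fits are exact on polynomial data", {
  x <- rep(c(0.25, 0.5, 1, 1.5, 2), each = 3)
  y <- 2 + 3 * x
  f <- fit_trend(x, y, degree = 1, B = 0)
  expect_equal(f$coefficients, c(2, 3))
  expect_equal(f$fitted, 2 + 3 * f$x_out)
  fc <- fit_trend(x, rep(5, length(x)), degree = 3, B = 0)
  expect_equal(fc$coefficients[2:4], rep(0, 3), tolerance = 1e-8)
  expect_error(fit_trend(c(1, 1, 2, 2), c(1, 2, 3, 4), degree = 2),
               "degenerate design")
})

test_that("stability correction is identity for flat ratios and recovers truth", {
  cond <- default_conditions()
  qpcr_flat <- data.frame(mu = rep(cond$mu, each = 8), ratio = 1)
  sc <- stability_correction(qpcr_flat, B = 0)
  expect_equal(sc$ratio_fun(cond$mu), rep(1, 8), tolerance = 1e-9)
  expect_equal(sc$correct(c(2, 3), c(0.4, 0.8)), c(2, 3), tolerance = 1e-9)
  expect_error(stability_correction(data.frame(mu = cond$mu, ratio = -1)),
               "nonpositive")

  # declining-stability round trip: corrected lambda recovers truth,
  # uncorrected does not
  declining <- function(mu) 1 - 0.4 * (mu - 0.25) / 1.45
  tr <- make_truth(noise_cv = 0, seed = 12,
                   stability_truth = stats::setNames(
                     rep(list(declining), 6), names(default_reporter_truth())))
  lib <- generate_reporter_library(tr)
  s <- "fbaA_short"
  fl <- lib$fluorescence[lib$fluorescence$strain == s, ]
  qp <- lib$qpcr[lib$qpcr$strain == s, ]
  sc2 <- stability_correction(qp, B = 0)
  mref <- lib$reference_mrna
  corrected <- data.frame(condition = mref$condition,
                          abundance = sc2$correct(mref$abundance, mref$mu))
  uncorrected <- data.frame(condition = mref$condition, abundance = mref$abundance)
  lam_truth <- translation_efficiency(tr$tir_truth[[s]], tr$rfree_truth$values)
  prof_c <- efficiency_profile(fl, corrected, B = 0)
  prof_u <- efficiency_profile(fl, uncorrected, B = 0)
  expect_equal(prof_c$lambda, unname(lam_truth[prof_c$condition]), tolerance = 1e-6)
  err_u <- abs(prof_u$lambda - lam_truth[prof_u$condition]) / lam_truth[prof_u$condition]
  expect_gt(max(err_u), 0.2)
})

test_that("efficiency profiles compute lambda = mu P / m with exact identities", {
  fl <- data.frame(condition = "c1", mu = 0.4, replicate = 1:2, value = 10)
  m <- data.frame(condition = "c1", abundance = 2)
  expect_equal(efficiency_profile(fl, m, B = 0)$lambda, 2.0)
  expect_error(efficiency_profile(fl, data.frame(condition = "c1", abundance = 0)),
               "zero mRNA")
  # noiseless generator data: lambda equals truth to machine precision
  tr <- make_truth(noise_cv = 0, seed = 2)
  lib <- generate_reporter_library(tr)
  mref <- data.frame(condition = lib$reference_mrna$condition,
                     abundance = lib$reference_mrna$abundance)
  for (s in c("fbaA_fbaA", "hs_modif1")) {
    fl_s <- lib$fluorescence[lib$fluorescence$strain == s, ]
    prof <- efficiency_profile(fl_s, mref, B = 0)
    lam_truth <- translation_efficiency(tr$tir_truth[[s]], tr$rfree_truth$values)
    expect_equal(prof$lambda, unname(lam_truth[prof$condition]), tolerance = 1e-12)
    # P1/P2 = (lambda1/lambda2)(m1/m2)(mu2/mu1) on the outputs
    p <- vapply(split(fl_s$value, fl_s$condition), mean, numeric(1))[prof$condition]
    m_c <- stats::setNames(mref$abundance, mref$condition)[prof$condition]
    expect_equal(unname(p[1] / p[2]),
                 (prof$lambda[1] / prof$lambda[2]) * unname(m_c[1] / m_c[2]) *
                   (prof$mu[2] / prof$mu[1]))
  }
})

test_that("the MSE ratio estimator is exact, scale-equivariant and unit on a = b", {
  tr <- make_truth(noise_cv = 0.05, seed = 21)
  lib <- generate_reporter_library(tr)
  fa <- lib$fluorescence[lib$fluorescence$strain == "fbaA_short", ]
  # a = b: unity up to the small variance bias of LS through the origin
  # (exactly (sum P)^2 / (n sum P^2) = 1 / (1 + cv^2 (n-1)/n) on itself)
  er_same <- efficiency_ratio(fa, fa, B = 0)
  expect_equal(er_same$ratio, rep(1, 8), tolerance = 0.01)
  fb <- lib$fluorescence[lib$fluorescence$strain == "fbaA_modif1", ]
  r1 <- efficiency_ratio(fa, fb, B = 0)
  fa2 <- fa; fa2$value <- 3 * fa2$value
  r2 <- efficiency_ratio(fa2, fb, B = 0)
  expect_equal(r2$ratio, 3 * r1$ratio)
  fb_drop <- fb[fb$condition != "CHG", ]
  expect_error(efficiency_ratio(fa, fb_drop, B = 0), "CHG")
})

test_that("the short/linear efficiency ratio doubles as free ribosomes drop", {
  # truth with R from 0.7 to 0.2: lambda_short / lambda_linear rises 2-fold
  cond <- default_conditions()
  tr <- make_truth(noise_cv = 0, seed = 1,
                   rfree_truth = default_rfree_truth(
                     cond, anchors = c(`0.25` = 0.70, `1.7` = 0.20)))
  lib <- generate_reporter_library(tr)
  mref <- data.frame(condition = lib$reference_mrna$condition,
                     abundance = lib$reference_mrna$abundance)
  fa <- lib$fluorescence[lib$fluorescence$strain == "fbaA_short", ]
  fb <- lib$fluorescence[lib$fluorescence$strain == "hs_fbaA", ]
  er <- efficiency_ratio(fa, fb, mref, mref, B = 0)
  expect_equal(er$ratio[er$condition == "CHG"] / er$ratio[er$condition == "M9P"],
               2, tolerance = 1e-6)
})

test_that("a shallower free-ribosome drop attenuates the ratio change", {
  cond <- default_conditions()
  full <- make_truth(noise_cv = 0, seed = 1)
  shallow <- make_truth(noise_cv = 0, seed = 1,
                        rfree_truth = default_rfree_truth(
                          cond, anchors = c(`0.25` = 0.70, `1.7` = 0.45)))
  change <- function(tr) {
    lib <- generate_reporter_library(tr)
    fa <- lib$fluorescence[lib$fluorescence$strain == "fbaA_short", ]
    fb <- lib$fluorescence[lib$fluorescence$strain == "fbaA_modif1", ]
    er <- efficiency_ratio(fa, fb, B = 0)
    er$ratio[er$condition == "CHG"] / er$ratio[er$condition == "M9P"]
  }
  expect_gt(change(full), change(shallow))
  expect_gt(change(shallow), 1)
})
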