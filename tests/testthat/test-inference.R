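test_that("noiseless reporter data are recovered up to the gauge conventions", {
  tr <- make_truth(noise_cv = 0, seed = 7)
  d <- reporter_fit_data(tr)
  f <- joint_fit(d, gauge = "ref_ratio", ref_id = "hs_fbaA",
                 n_starts = 4, seed = 1)
  expect_lt(f$objective, 1e-8)
  # truth is expressed in the same gauge (hs_fbaA K1/K2 = 1): direct match
  expect_equal(unname(f$rfree$values), unname(tr$rfree_truth$values),
               tolerance = 1e-3)
  for (s in c("fbaA_fbaA", "fbaA_short", "fbaA_modif1")) {
    expect_equal(f$constants[[s]]$k1, tr$tir_truth[[s]]$k1, tolerance = 1e-2)
    expect_equal(f$constants[[s]]$k2, tr$tir_truth[[s]]$k2, tolerance = 1e-2)
  }
  # linear constructs: the K1/K2 ratio is the identified quantity
  for (s in c("hs_fbaA", "hs_modif1", "hs_modif2")) {
    expect_equal(f$constants[[s]]$k1 / f$constants[[s]]$k2,
                 tr$tir_truth[[s]]$k1 / tr$tir_truth[[s]]$k2, tolerance = 1e-3)
  }
})

test_that("the fit is invariant under the (R, K2) scale gauge", {
  tr <- make_truth(noise_cv = 0.05, seed = 13)
  d <- reporter_fit_data(tr)
  f1 <- joint_fit(d, gauge = "ref_ratio", ref_id = "hs_fbaA", n_starts = 3, seed = 2)
  f2 <- joint_fit(d, gauge = "anchor_slowest", n_starts = 3, seed = 2)
  # same objective; lambda predictions identical to machine precision
  expect_equal(f1$objective, f2$objective, tolerance = 1e-12)
  lam <- function(f) t(vapply(f$constants, function(cs)
    translation_efficiency(cs, f$rfree$values), numeric(8)))
  expect_equal(lam(f1), lam(f2), tolerance = 1e-9)
  # and the anchor gauge does what it says
  expect_equal(unname(f2$rfree$values[1]), 1.0)
  # data generated from a rescaled truth (cR, cK2) are identical by algebra
  r <- tr$rfree_truth$values
  for (s in names(tr$tir_truth)) {
    cs <- tr$tir_truth[[s]]
    expect_equal(translation_efficiency(cs, r),
                 translation_efficiency(tir_constants(cs$k1, 3 * cs$k2), 3 * r))
  }
})

test_that("the alternating optimizer descends monotonically", {
  tr <- make_truth(noise_cv = 0.05, seed = 17)
  f <- joint_fit(reporter_fit_data(tr), gauge = "ref_ratio", ref_id = "hs_fbaA",
                 n_starts = 2, seed = 3)
  tr_obj <- f$objective_trace
  expect_true(all(diff(tr_obj) <= 1e-9 * (1 + tr_obj[-length(tr_obj)])))
  expect_true(f$diagnostics$converged)
})

test_that("saturation classes follow the threshold rule and the gauge", {
  cond <- default_conditions()
  r <- rfree_trajectory(seq(0.7, 0.2, length.out = 8)[order(cond$mu)],
                        cond, gauge = "ref_ratio")
  r$values <- stats::setNames(seq(0.7, 0.2, length.out = 8), cond$name)
  expect_equal(classify_transcript(tir_constants(1, 0), r), "saturated")
  expect_equal(classify_transcript(tir_constants(1, 100 * max(r$values)), r),
               "undersaturated")
  expect_equal(classify_transcript(tir_constants(1, 0.3), r), "unsaturated")
  # gauge invariance: scaling K2 and R together preserves the label
  r2 <- r; r2$values <- 5 * r$values
  expect_equal(classify_transcript(tir_constants(1, 5 * 0.3), r2), "unsaturated")
  expect_equal(classify_transcript(tir_constants(1, 5 * 0), r2), "saturated")
})

test_that("noiseless genome-wide fits recover every class label and filter genes", {
  tr <- make_truth(noise_cv = 0, seed = 5)
  panel <- generate_omics(tr, n_genes = 60,
                          class_proportions = c(0.3, 0.5, 0.2), replicates = 2)
  # knock one gene below the detection filter (2 conditions left)
  panel$detected[3, 3:8] <- FALSE
  gw <- genome_wide_fit(panel, seed = 1, n_starts = 2)
  expect_equal(gw$excluded, panel$genes[3])
  keep <- setdiff(panel$genes, gw$excluded)
  got <- gw$class_table$class[match(keep, gw$class_table$gene)]
  expect_equal(got, unname(panel$classes[keep]))
  # efficiency profiles are anchored at the slowest condition
  expect_true(all(abs(gw$efficiency_profiles[, 1] - 1) < 1e-12))
})

test_that("K2 of unsaturated transcripts is recovered within 20% at study noise", {
  # a full panel: the undersaturated quota pins the reciprocal-shift
  # convention, so finite K2 values are comparable to truth
  tr <- make_truth(noise_cv = 0.05, seed = 23)
  panel <- generate_omics(tr, n_genes = 100,
                          class_proportions = c(0.2, 0.6, 0.2),
                          replicates = 24)
  gw <- genome_wide_fit(panel, seed = 1, n_starts = 3)
  uns <- names(panel$classes)[panel$classes == "unsaturated"]
  k2_hat <- gw$class_table$k2[match(uns, gw$class_table$gene)]
  k2_true <- vapply(panel$constants[uns], `[[`, numeric(1), "k2")
  # put the estimate in the truth gauge via the R trajectories
  scale <- tr$rfree_truth$values[1] / gw$fit$rfree$values[1]
  rel_err <- abs(k2_hat * scale - k2_true) / k2_true
  expect_lt(stats::median(rel_err), 0.2)
})

test_that("perturbed free-ribosome trajectories are re-inferred with clamped constants", {
  tr <- make_truth(noise_cv = 0, seed = 31)
  d <- reporter_fit_data(tr)
  f <- joint_fit(d, gauge = "ref_ratio", ref_id = "hs_fbaA", n_starts = 3, seed = 1)
  # identical data: identical trajectory
  same <- infer_perturbed_rfree(d, f$constants, unperturbed = f$rfree)
  expect_equal(unname(same$rfree$values), unname(f$rfree$values), tolerance = 1e-6)
  expect_true(all(abs(same$fold_change - 1) < 1e-6))
  # a perturbation that halves R everywhere is recovered as a twofold drop
  tr2 <- make_truth(noise_cv = 0, seed = 31)
  tr2$rfree_truth$values <- tr$rfree_truth$values / 2
  d2 <- reporter_fit_data(tr2)
  pert <- infer_perturbed_rfree(d2, f$constants, unperturbed = f$rfree)
  expect_equal(unname(pert$fold_change), rep(0.5, 8), tolerance = 1e-3)
  # an attenuated drop leaves fast-growth R above the unperturbed value
  tr3 <- make_truth(noise_cv = 0, seed = 31,
                    rfree_truth = default_rfree_truth(
                      default_conditions(),
                      anchors = c(`0.25` = 0.70, `1.7` = 0.40)))
  d3 <- reporter_fit_data(tr3)
  att <- infer_perturbed_rfree(d3, f$constants, unperturbed = f$rfree)
  fastest <- c("TS", "CH", "CHG")
  expect_true(all(att$rfree$values[fastest] >= f$rfree$values[fastest]))
})

test_that("class over-representation p-values match exhaustive hypergeometric sums", {
  # brute-force oracle: P(overlap >= k) by direct summation of choose() terms
  brute <- function(k, marked, universe, class_size) {
    kk <- k:min(marked, class_size)
    sum(choose(marked, kk) * choose(universe - marked, class_size - kk)) /
      choose(universe, class_size)
  }
  tab <- data.frame(gene = sprintf("g%02d", 1:20),
                    class = rep(c("saturated", "unsaturated"), each = 10))
  marked <- sprintf("g%02d", 1:10)  # full overlap with the saturated class
  res <- long_utr_enrichment(tab, marked)
  expect_equal(res$p_value[res$class == "saturated"],
               brute(10, 10, 20, 10))
  # overlap 9 toy case
  marked9 <- c(sprintf("g%02d", 1:9), "g11")
  res9 <- long_utr_enrichment(tab, marked9)
  expect_equal(res9$p_value[res9$class == "saturated"], brute(9, 10, 20, 10))
  expect_equal(res9$overlap[res9$class == "saturated"], 9)
  # zero overlap: over-representation side gives p = 1
  expect_equal(res$p_value[res$class == "undersaturated"], 1)
  expect_warning(out <- long_utr_enrichment(tab, character(0)), "empty")
  expect_true(all(out$p_value == 1))
  # the study-scale fixture: 71 marked genes in a 1,002-gene universe
  big <- data.frame(gene = sprintf("g%04d", 1:1002),
                    class = rep(c("saturated", "unsaturated", "undersaturated"),
                                c(223, 698, 81)))
  set.seed(99)
  res_big <- long_utr_enrichment(big, sample(big$gene, 71))
  expect_equal(nrow(res_big), 3)
  expect_true(all(res_big$p_value >= 0 & res_big$p_value <= 1))
})
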