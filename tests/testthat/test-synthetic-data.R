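test_that("the default condition grid matches the eight study media", {
  cond <- default_conditions()
  expect_equal(nrow(cond), 8)
  expect_equal(cond$name[1], "M9P"); expect_equal(cond$mu[1], 0.25)
  expect_equal(cond$name[8], "CHG"); expect_equal(cond$mu[8], 1.70)
  expect_true(all(cond$mu > 0))
  expect_false(is.unsorted(cond$mu))
})

test_that("generation is a pure function of truth and seed", {
  tr <- make_truth(noise_cv = 0.05, seed = 9)
  expect_identical(generate_reporter_library(tr), generate_reporter_library(tr))
  expect_identical(generate_omics(tr, n_genes = 30), generate_omics(tr, n_genes = 30))
  expect_identical(generate_spikein_arrays(tr), generate_spikein_arrays(tr))
})

test_that("at zero noise every observable equals its closed-form value", {
  tr <- make_truth(noise_cv = 0, seed = 2)
  lib <- generate_reporter_library(tr)
  for (s in names(tr$tir_truth)) {
    lam <- translation_efficiency(tr$tir_truth[[s]], tr$rfree_truth$values)
    p_true <- protein_abundance(tr$transcript_truth[[s]], lam,
                                tr$conditions$mu)
    d <- lib$fluorescence[lib$fluorescence$strain == s, ]
    by_cond <- split(d$value, d$condition)
    for (cc in names(by_cond)) {
      expect_true(all(by_cond[[cc]] == by_cond[[cc]][1]))  # replicates identical
      expect_equal(unname(by_cond[[cc]][1]), unname(p_true[cc]))
    }
  }
  expect_true(all(lib$fluorescence$value > 0))
  expect_true(all(lib$qpcr$ratio == 1))  # default stability truth is flat
})

test_that("the reporter truth reproduces the twofold short/linear ratio shift", {
  # short TIR: K2 = 0.3; a linear construct cancels R; the efficiency ratio
  # between them rises exactly 2-fold as R drops 0.7 -> 0.2
  anchors <- c(`0.25` = 0.70, `1.7` = 0.20)
  cond <- default_conditions()
  tr <- make_truth(noise_cv = 0, seed = 1,
                   rfree_truth = default_rfree_truth(cond, anchors = anchors))
  short <- tr$tir_truth$fbaA_short; lin <- tr$tir_truth$hs_fbaA
  r <- tr$rfree_truth$values
  ratio <- translation_efficiency(short, r) / translation_efficiency(lin, r)
  expect_equal(unname(ratio[["CHG"]] / ratio[["M9P"]]), 2, tolerance = 1e-6)
})

test_that("omics panels honour quota class assignment and class K2 ranges", {
  tr <- make_truth(noise_cv = 0.05, seed = 5)
  panel <- generate_omics(tr, n_genes = 1002,
                          class_proportions = c(223, 698, 81) / 1002)
  counts <- table(factor(panel$classes,
    levels = c("saturated", "unsaturated", "undersaturated")))
  expect_equal(unname(c(counts)), c(223, 698, 81))
  r <- tr$rfree_truth$values
  k2 <- vapply(panel$constants, `[[`, numeric(1), "k2")
  expect_true(all(k2[panel$classes == "saturated"] <= 0.01 * min(r)))
  expect_true(all(k2[panel$classes == "undersaturated"] >= 100 * max(r)))
  uns <- k2[panel$classes == "unsaturated"]
  expect_true(all(uns >= min(r) / 3 & uns <= 3 * max(r)))
  expect_true(all(panel$transcript > 0) && all(panel$protein > 0))
})

test_that("saturated-only noiseless panels satisfy P = K1 m / mu exactly", {
  tr <- make_truth(noise_cv = 0, seed = 3)
  panel <- generate_omics(tr, n_genes = 3, class_proportions = c(1, 0, 0),
                          replicates = 2)
  for (g in panel$genes) {
    cs <- panel$constants[[g]]
    lam <- translation_efficiency(cs, tr$rfree_truth$values)
    for (k in 1:2) {
      # exact generative law P = m lambda / mu ...
      expect_equal(panel$protein[g, , k],
                   panel$transcript[g, , k] * lam / tr$conditions$mu,
                   tolerance = 1e-12)
      # ... and the saturated limit P = K1 m / mu to within the drawn
      # K2 <= 0.01 min R (relative error at most 1%)
      expect_equal(panel$protein[g, , k],
                   cs$k1 * panel$transcript[g, , k] / tr$conditions$mu,
                   tolerance = 0.01)
    }
  }
})

test_that("spike-in arrays carry ten spikes and scale with the library factor", {
  tr <- make_truth(noise_cv = 0, seed = 8)
  a1 <- generate_spikein_arrays(tr, library_scale = 1)
  a2 <- generate_spikein_arrays(tr, library_scale = 2)
  expect_true(all(vapply(a1, function(a) length(a$spike_intensities), numeric(1)) == 10))
  for (i in seq_along(a1)) {
    expect_equal(a2[[i]]$probe_intensities, 2 * a1[[i]]$probe_intensities)
    expect_equal(a2[[i]]$spike_intensities, 2 * a1[[i]]$spike_intensities)
  }
  # spike amounts identical across arrays at noise zero
  smat <- vapply(a1, `[[`, numeric(10), "spike_intensities")
  expect_true(all(abs(smat - smat[, 1]) < 1e-12))
})
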