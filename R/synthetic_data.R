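#' Declared ground truth for the synthetic-data generator
#'
#' Bundles everything the generator needs: the condition grid, the true
#' free-ribosome trajectory, per-strain/per-gene translation constants,
#' transcript trajectories, the RNA composition, the noise model and the
#' replicate structure. Generation is a pure function of (truth, seed).
#'
#' @param conditions a `growth_conditions` set (default [default_conditions()]).
#' @param rfree_truth an `rfree_trajectory` (default
#'   [default_rfree_truth()] on `conditions`).
#' @param tir_truth named list of `tir_constants`, one per strain/gene
#'   (default [default_reporter_truth()]).
#' @param transcript_truth named list: gene -> abundance per condition (AU).
#'   Default: reference transcript proportional to growth rate, normalized to
#'   1 at the slowest condition, for every strain in `tir_truth`.
#' @param stability_truth named list: strain -> function(mu) giving the true
#'   reporter/reference mRNA ratio. Default: identically 1.
#' @param mrna_fraction,rrna_fraction,trna_fraction fractions of total RNA
#'   (defaults 0.05 / 0.85 / 0.10; constant across conditions as measured).
#' @param rrna_split fractions of *total RNA* in the 23S/16S/5S sub-species
#'   (must sum to `rrna_fraction`).
#' @param total_rna_slope total RNA mass per OD600 per unit growth rate
#'   (total RNA proportional to mu, the measured first-order behaviour).
#' @param noise_cv multiplicative log-normal coefficient of variation
#'   (default 0.05).
#' @param replicates fluorescence replicates per condition (default 24:
#'   12 technical x 2 biological).
#' @param qpcr_replicates qPCR replicates per condition (default 8).
#' @param seed integer seed recorded with the truth.
#' @return An object of class `generator_truth`.
#' @export
generator_truth <- function(conditions = default_conditions(),
                            rfree_truth = default_rfree_truth(conditions),
                            tir_truth = default_reporter_truth(),
                            transcript_truth = NULL,
                            stability_truth = NULL,
                            mrna_fraction = 0.05,
                            rrna_fraction = 0.85,
                            trna_fraction = 0.10,
                            rrna_split = c(`23S` = 0.53, `16S` = 0.28, `5S` = 0.04),
                            total_rna_slope = 100,
                            noise_cv = 0.05,
                            replicates = 24,
                            qpcr_replicates = 8,
                            seed = 1L) {
  stopifnot(inherits(conditions, "growth_conditions"),
            inherits(rfree_truth, "rfree_trajectory"))
  fr <- c(mrna_fraction, rrna_fraction, trna_fraction)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1 + 1e-9)
    stop("RNA fractions must lie in [0,1] and sum to at most 1")
  if (abs(sum(rrna_split) - rrna_fraction) > 1e-9)
    stop("rrna_split must sum to rrna_fraction")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (replicates < 1 || qpcr_replicates < 1) stop("replicates must be >= 1")
  if (is.null(transcript_truth)) {
    m <- conditions$mu / min(conditions$mu)
    names(m) <- conditions$name
    transcript_truth <- stats::setNames(
      rep(list(m), length(tir_truth)), names(tir_truth))
  }
  if (is.null(stability_truth)) {
    stability_truth <- stats::setNames(
      rep(list(function(mu) rep(1, length(mu))), length(tir_truth)),
      names(tir_truth))
  }
  structure(list(conditions = conditions, rfree_truth = rfree_truth,
                 tir_truth = tir_truth, transcript_truth = transcript_truth,
                 stability_truth = stability_truth,
                 mrna_fraction = mrna_fraction, rrna_fraction = rrna_fraction,
                 trna_fraction = trna_fraction, rrna_split = rrna_split,
                 total_rna_slope = total_rna_slope,
                 noise_cv = noise_cv, replicates = replicates,
                 qpcr_replicates = qpcr_replicates, seed = as.integer(seed)),
            class = "generator_truth")
}

#' Default ground-truth free-ribosome trajectory
#'
#' A sharp drop of the free-ribosome abundance between 0.25 and 1.2 h^-1
#' followed by a plateau, interpolated through declared anchors by a
#' monotone (Hyman-filtered) cubic. The default anchors give a 4.4-fold
#' total drop (0.70 at the slowest condition down to 0.16), consistent with
#' an "at least fourfold" decrease, and keep 0.3 inside the spanned range.
#' Anchors are configuration, not hard-coded behaviour.
#'
#' @param conditions a `growth_conditions` set.
#' @param anchors named numeric vector of R values at anchor growth rates
#'   (names are the mu values).
#' @param gauge gauge convention recorded on the trajectory.
#' @return An `rfree_trajectory` evaluated on the condition grid.
#' @export
default_rfree_truth <- function(conditions = default_conditions(),
                                anchors = c(`0.25` = 0.70, `0.6` = 0.40,
                                            `0.9` = 0.26, `1.2` = 0.17,
                                            `1.7` = 0.16),
                                gauge = "ref_ratio") {
  mu_a <- as.numeric(names(anchors))
  if (is.unsorted(mu_a)) stop("anchor growth rates must be increasing")
  interp <- stats::splinefun(mu_a, anchors, method = "hyman")
  mu <- pmin(pmax(conditions$mu, min(mu_a)), max(mu_a))
  rfree_trajectory(interp(mu), conditions, gauge = gauge)
}

#' Default reporter-library truth constants
#'
#' Six TIR constructs calibrated to the fitted reporter-library behaviour:
#' the short-TIR construct has K2 = 0.3 (inside the free-ribosome range, a
#' twofold efficiency drop), the modif1 construct K2 = 7.5 (25-fold above
#' short, efficiency tracking R), and three reference-promoter constructs
#' that are effectively linear in R (K2 far above any attainable R; only
#' their K1/K2 ratio is meaningful). Constants are expressed in the gauge
#' where K1/K2 of `hs_fbaA` equals 1.
#'
#' @return Named list of `tir_constants`.
#' @export
default_reporter_truth <- function() {
  lin <- 1e9  # K2 >> R: lambda = (K1/K2) R to within 1e-9
  list(
    fbaA_fbaA   = tir_constants(2.2, 2.0),
    fbaA_short  = tir_constants(1.0, 0.3),
    fbaA_modif1 = tir_constants(8.0, 7.5),
    hs_fbaA     = tir_constants(1.0 * lin, lin),
    hs_modif1   = tir_constants(1.5 * lin, lin),
    hs_modif2   = tir_constants(0.67 * lin, lin)
  )
}

# multiplicative log-normal noise with unit mean and the stated CV
lnorm_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a reporter-library dataset
#'
#' Emulates the live-cell-array + qPCR design: for each strain the true
#' reporter mRNA is the reference transcript trajectory times the declared
#' stability curve; fluorescence per replicate is
#' `P = m * lambda(K1, K2, R_truth) / mu` under multiplicative log-normal
#' noise, and the qPCR table encodes the stability curves plus noise.
#'
#' @param truth a `generator_truth`.
#' @return List with `fluorescence` (strain, condition, mu, replicate,
#'   value), `qpcr` (strain, condition, mu, replicate, ratio) and
#'   `reference_mrna` (condition, mu, abundance) data frames.
#' @export
generate_reporter_library <- function(truth) {
  stopifnot(inherits(truth, "generator_truth"))
  set.seed(truth$seed)
  cond <- truth$conditions
  strains <- names(truth$tir_truth)
  missing_m <- setdiff(strains, names(truth$transcript_truth))
  if (length(missing_m))
    stop("no transcript truth for strain(s): ", paste(missing_m, collapse = ", "))
  fluor <- list(); qpcr <- list()
  for (s in strains) {
    consts <- truth$tir_truth[[s]]
    stab <- truth$stability_truth[[s]](cond$mu)
    m_ref <- truth$transcript_truth[[s]]
    m <- m_ref * stab
    lam <- translation_efficiency(consts, truth$rfree_truth$values)
    p <- protein_abundance(m, lam, cond$mu)
    for (i in seq_len(nrow(cond))) {
      nz <- lnorm_noise(truth$replicates, truth$noise_cv)
      fluor[[length(fluor) + 1L]] <- data.frame(
        strain = s, condition = cond$name[i], mu = cond$mu[i],
        replicate = seq_len(truth$replicates), value = p[i] * nz,
        stringsAsFactors = FALSE)
      nq <- lnorm_noise(truth$qpcr_replicates, truth$noise_cv)
      qpcr[[length(qpcr) + 1L]] <- data.frame(
        strain = s, condition = cond$name[i], mu = cond$mu[i],
        replicate = seq_len(truth$qpcr_replicates), ratio = stab[i] * nq,
        stringsAsFactors = FALSE)
    }
  }
  ref <- truth$transcript_truth[[strains[1]]]
  list(fluorescence = do.call(rbind, fluor),
       qpcr = do.call(rbind, qpcr),
       reference_mrna = data.frame(condition = cond$name, mu = cond$mu,
                                   abundance = unname(ref),
                                   stringsAsFactors = FALSE))
}

#' Generate a paired transcriptome/proteome panel
#'
#' Assigns each gene a saturation class by deterministic quota in the given
#' proportions, draws class-consistent \{K1, K2\} pairs (saturated:
#' K2 <= 0.01 min R; unsaturated: K2 in [min R / 3, 3 max R]; undersaturated:
#' K2 >= 100 max R), draws transcript trajectories, and computes proteins via
#' `P = m * lambda / mu` with multiplicative noise. The class-conditional K2
#' ranges are a modelling device needed to emulate the observed class
#' structure, not a measured quantity.
#'
#' @param truth a `generator_truth`.
#' @param n_genes number of genes (default 1002).
#' @param class_proportions proportions (saturated, unsaturated,
#'   undersaturated); default the reported 223/698/81 split.
#' @param replicates replicate measurements per gene and condition.
#' @param missingness probability that a gene-condition pair is undetected.
#' @return An `omics_panel`: list with `genes`, `classes` (truth labels),
#'   `constants` (list of `tir_constants`), `transcript` and `protein`
#'   (gene x condition x replicate arrays), `detected` (gene x condition
#'   logical), `conditions`.
#' @export
generate_omics <- function(truth, n_genes = 1002,
                           class_proportions = c(223, 698, 81) / 1002,
                           replicates = 3, missingness = 0) {
  stopifnot(inherits(truth, "generator_truth"))
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (length(class_proportions) != 3 || any(class_proportions < 0) ||
      abs(sum(class_proportions) - 1) > 1e-9)
    stop("class_proportions must be three nonnegative values summing to 1")
  set.seed(truth$seed + 1L)
  cond <- truth$conditions
  nc <- nrow(cond)
  r <- truth$rfree_truth$values
  rmin <- min(r); rmax <- max(r)
  # deterministic quota assignment: largest-remainder rounding
  counts <- floor(n_genes * class_proportions)
  rem <- n_genes - sum(counts)
  if (rem > 0) {
    frac <- n_genes * class_proportions - counts
    counts[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1L
  }
  classes <- rep(c("saturated", "unsaturated", "undersaturated"), counts)
  genes <- sprintf("g%04d", seq_len(n_genes))
  constants <- vector("list", n_genes); names(constants) <- genes
  k1 <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 0.8)
  k2 <- numeric(n_genes)
  for (i in seq_len(n_genes)) {
    k2[i] <- switch(classes[i],
      saturated      = stats::runif(1, 0, 0.01 * rmin),
      unsaturated    = exp(stats::runif(1, log(rmin / 3), log(3 * rmax))),
      undersaturated = exp(stats::runif(1, log(100 * rmax), log(1000 * rmax))))
    constants[[i]] <- tir_constants(k1[i], k2[i], classes[i])
  }
  # transcript trajectories: gene-specific baseline times a gene-specific
  # power of the growth-rate fold (exponents 0..2: from flat to super-linear)
  base <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 0.5)
  expo <- stats::runif(n_genes, 0, 2)
  mu_fold <- cond$mu / min(cond$mu)
  transcript <- array(NA_real_, dim = c(n_genes, nc, replicates),
                      dimnames = list(genes, cond$name, NULL))
  protein <- transcript
  for (i in seq_len(n_genes)) {
    m_true <- base[i] * mu_fold^expo[i]
    lam <- translation_efficiency(constants[[i]], r)
    p_true <- protein_abundance(m_true, lam, cond$mu)
    for (k in seq_len(replicates)) {
      transcript[i, , k] <- m_true * lnorm_noise(nc, truth$noise_cv)
      protein[i, , k] <- p_true * lnorm_noise(nc, truth$noise_cv)
    }
  }
  detected <- matrix(stats::runif(n_genes * nc) >= missingness,
                     nrow = n_genes, dimnames = list(genes, cond$name))
  structure(list(genes = genes, classes = stats::setNames(classes, genes),
                 constants = constants, transcript = transcript,
                 protein = protein, detected = detected, conditions = cond),
            class = "omics_panel")
}

#' Generate spike-in expression arrays
#'
#' One array per condition. Total RNA per OD is proportional to the growth
#' rate; a fixed mass of total RNA is hybridized per array together with a
#' set of ten in vitro-synthesized spike transcripts added in identical
#' amounts to every array. Intensities are proportional to the amounts in
#' the aliquot times a per-array library scale; noise is applied last.
#'
#' @param truth a `generator_truth`.
#' @param library_scale per-array multiplicative factor (scalar or one per
#'   condition; default 1).
#' @param n_spikes number of spike-in probes (default 10).
#' @param n_genes number of endogenous genes on the array (default 200).
#' @param aliquot_mass mass of total RNA hybridized per array (default 10).
#' @return List of `spikein_array` objects (one per condition), each with
#'   `condition`, `mu`, `probe_intensities`, `spike_intensities`,
#'   `total_rna_per_od`.
#' @export
generate_spikein_arrays <- function(truth, library_scale = 1,
                                    n_spikes = 10, n_genes = 200,
                                    aliquot_mass = 10) {
  stopifnot(inherits(truth, "generator_truth"))
  cond <- truth$conditions
  nc <- nrow(cond)
  library_scale <- rep_len(library_scale, nc)
  if (any(library_scale <= 0)) stop("library_scale must be > 0")
  set.seed(truth$seed + 2L)
  genes <- sprintf("g%04d", seq_len(n_genes))
  spikes <- sprintf("spike%02d", seq_len(n_spikes))
  # spike amounts: fixed across arrays (the design's anchor)
  s_amount <- stats::rlnorm(n_spikes, meanlog = 0, sdlog = 0.3)
  # gene shares of the mRNA pool per condition (allowed to reorganize)
  base <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1)
  expo <- stats::runif(n_genes, 0, 2)
  out <- vector("list", nc)
  for (i in seq_len(nc)) {
    total_rna <- truth$total_rna_slope * cond$mu[i]
    w <- base * (cond$mu[i] / min(cond$mu))^expo
    share <- w / sum(w)                       # gene share of mRNA mass
    mrna_in_aliquot <- aliquot_mass * truth$mrna_fraction
    gene_amount <- mrna_in_aliquot * share
    probe <- gene_amount * library_scale[i] *
      lnorm_noise(n_genes, truth$noise_cv)
    spike <- s_amount * library_scale[i] *
      lnorm_noise(n_spikes, truth$noise_cv)
    names(probe) <- genes; names(spike) <- spikes
    out[[i]] <- structure(list(condition = cond$name[i], mu = cond$mu[i],
                               probe_intensities = probe,
                               spike_intensities = spike,
                               total_rna_per_od = total_rna),
                          class = "spikein_array")
  }
  names(out) <- cond$name
  out
}

#' Generate RNA-composition measurements
#'
#' Per-condition replicate measurements of the fractions of total RNA in the
#' 23S/16S/5S rRNA species, tRNA and mRNA, under multiplicative noise around
#' the declared (condition-independent) composition truth.
#'
#' @param truth a `generator_truth`.
#' @param replicates measurements per condition (default 4).
#' @param noise_cv measurement CV (default `truth$noise_cv`).
#' @return Data frame (condition, mu, replicate, species, fraction).
#' @export
generate_rna_composition <- function(truth, replicates = 4,
                                     noise_cv = truth$noise_cv) {
  stopifnot(inherits(truth, "generator_truth"))
  set.seed(truth$seed + 3L)
  cond <- truth$conditions
  species <- c(names(truth$rrna_split), "tRNA", "mRNA")
  true_frac <- c(truth$rrna_split, tRNA = unname(truth$trna_fraction),
                 mRNA = unname(truth$mrna_fraction))
  rows <- list()
  for (i in seq_len(nrow(cond))) {
    for (k in seq_len(replicates)) {
      fr <- true_frac * lnorm_noise(length(true_frac), noise_cv)
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond$name[i], mu = cond$mu[i], replicate = k,
        species = species, fraction = unname(fr), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
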