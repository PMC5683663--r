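#' Per-array scaling factors from spike-in probes
#'
#' Every array carries the same absolute amount of each spike-in transcript,
#' so the spike intensities expose the per-array global (library) scale. For
#' array a the factor is
#' `1 / median_i( spike[a, i] / geometric-mean_a'( spike[a', i] ) )`,
#' i.e. the reciprocal of the array's median spike ratio against the
#' cross-array geometric-mean reference; factors are then mean-normalized to
#' average 1. Multiplying corrected signals by the factor removes the
#' library scale. The median across spikes is robust to a single failed
#' probe.
#'
#' @param arrays list of `spikein_array` objects sharing the spike probes.
#' @return Named numeric vector of factors, one per array, mean 1.
#' @export
scaling_factor <- function(arrays) {
  if (length(arrays) < 1) stop("need at least one array")
  spike_ids <- Reduce(intersect, lapply(arrays, function(a) names(a$spike_intensities)))
  if (length(spike_ids) < 1) stop("arrays share no spike-in probe")
  s <- t(vapply(arrays, function(a) a$spike_intensities[spike_ids],
                numeric(length(spike_ids))))
  bad <- which(s <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("nonpositive spike intensity: probe %s on array %s",
                 spike_ids[bad[1, 2]], names(arrays)[bad[1, 1]]))
  ref <- exp(colMeans(log(s)))            # geometric mean per spike
  raw <- 1 / apply(sweep(s, 2, ref, "/"), 1, stats::median)
  f <- raw / mean(raw)
  names(f) <- names(arrays)
  f
}

#' Total mRNA abundance per condition from spike-in arrays
#'
#' Combines the scale-corrected summed mRNA signal of each array (the mRNA
#' fraction of the hybridized aliquot, free of the library scale) with the
#' measured total RNA per OD: total mRNA_c is proportional to
#' `factor_c * sum(probe signal_c) * total RNA_c`. The result is reported
#' normalized so the anchor condition (the 0.4 h^-1 medium by default)
#' equals 1.0.
#'
#' @param arrays list of `spikein_array` objects.
#' @param factors per-array factors from [scaling_factor()].
#' @param total_rna_per_od optional total RNA per OD per condition; defaults
#'   to the values carried on the arrays.
#' @param anchor condition name to anchor at 1.0 (default the condition with
#'   `mu` == 0.4 if present, otherwise an explicit name is required).
#' @return Data frame (condition, mu, total_mrna) with anchor == 1.
#' @export
total_mrna_abundance <- function(arrays, factors = scaling_factor(arrays),
                                 total_rna_per_od = NULL, anchor = NULL) {
  mu <- vapply(arrays, function(a) a$mu, numeric(1))
  cond <- vapply(arrays, function(a) a$condition, character(1))
  if (is.null(total_rna_per_od))
    total_rna_per_od <- vapply(arrays, function(a) a$total_rna_per_od, numeric(1))
  if (any(total_rna_per_od <= 0)) stop("total RNA values must be > 0")
  if (is.null(anchor)) {
    hit <- which(abs(mu - 0.4) < 1e-9)
    if (length(hit) != 1)
      stop("no condition at mu = 0.4; supply an explicit anchor condition")
    anchor <- cond[hit]
  }
  if (!anchor %in% cond) stop("anchor condition '", anchor, "' not present")
  signal <- vapply(arrays, function(a) sum(a$probe_intensities), numeric(1))
  tot <- factors * signal * total_rna_per_od
  tot <- tot / tot[match(anchor, cond)]
  data.frame(condition = cond, mu = mu, total_mrna = unname(tot),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Summarize RNA-species fractions across growth rates
#'
#' Fits each rRNA sub-species fraction with a degree-2 polynomial in mu and
#' the total rRNA fraction (sum of sub-species per measurement) with a
#' degree-1 polynomial, with bootstrap 95% bands over replicates.
#'
#' @param measurements data frame (condition, mu, replicate, species,
#'   fraction) as from [generate_rna_composition()]; rRNA species are those
#'   named in `rrna_species`.
#' @param rrna_species character vector naming the rRNA sub-species.
#' @param B bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return List with `fits` (per-species data frame of fitted fraction and
#'   95% band at each mu), `total_rrna` (same for the summed rRNA fraction)
#'   and `mean_rrna_percent` (mean fitted total-rRNA percentage over the
#'   grid).
#' @export
rna_species_summary <- function(measurements,
                                rrna_species = c("23S", "16S", "5S"),
                                B = 1000, seed = 1L) {
  need <- c("condition", "mu", "replicate", "species", "fraction")
  if (!all(need %in% names(measurements)))
    stop("measurements must have columns: ", paste(need, collapse = ", "))
  if (any(measurements$fraction < 0 | measurements$fraction > 1))
    stop("fractions must lie in [0, 1]")
  if (length(unique(measurements$mu)) < 2) stop("need at least 2 conditions")
  rr <- measurements[measurements$species %in% rrna_species, ]
  # total rRNA per (condition, replicate)
  tot <- stats::aggregate(fraction ~ condition + mu + replicate, data = rr, FUN = sum)
  mu_grid <- sort(unique(measurements$mu))
  fit_species <- function(df, degree) {
    fit_trend(df$mu, df$fraction, degree = degree, B = B, seed = seed,
              x_out = mu_grid)
  }
  fits <- lapply(rrna_species, function(sp) {
    df <- rr[rr$species == sp, ]
    f <- fit_species(df, degree = 2)
    data.frame(species = sp, mu = mu_grid, fitted = f$fitted,
               lower = f$lower, upper = f$upper, stringsAsFactors = FALSE)
  })
  names(fits) <- rrna_species
  ft <- fit_species(tot, degree = 1)
  total_rrna <- data.frame(mu = mu_grid, fitted = ft$fitted,
                           lower = ft$lower, upper = ft$upper)
  list(fits = fits, total_rrna = total_rrna,
       total_coefficients = ft$coefficients,
       mean_rrna_percent = 100 * mean(ft$fitted))
}

#' Two-group partition of the transcriptome between slow and fast growth
#'
#' A transcript is "enriched" when its fast/slow abundance ratio strictly
#' exceeds the total-mRNA fast/slow ratio (its abundance grew faster than
#' the mRNA pool), otherwise "depleted"; ties go to depleted. Genes with
#' zero slow-growth abundance cannot be ratio-tested and are excluded and
#' reported.
#'
#' @param slow,fast named per-gene abundances in the slow and fast condition.
#' @param total_ratio fast/slow total mRNA abundance ratio (> 0).
#' @return List with `groups` (named factor enriched/depleted),
#'   `mass_shares` (2 x 2 matrix: group x condition convex weights) and
#'   `excluded` (gene names with zero slow abundance).
#' @export
partition_transcripts <- function(slow, fast, total_ratio) {
  if (!identical(sort(names(slow)), sort(names(fast))))
    stop("slow and fast must cover the same gene set")
  if (total_ratio <= 0) stop("total_ratio must be > 0")
  fast <- fast[names(slow)]
  excluded <- names(slow)[slow == 0]
  keep <- setdiff(names(slow), excluded)
  ratio <- fast[keep] / slow[keep]
  groups <- factor(ifelse(ratio > total_ratio, "enriched", "depleted"),
                   levels = c("enriched", "depleted"))
  names(groups) <- keep
  share <- function(x) {
    g <- vapply(split(x[keep], groups), sum, numeric(1))
    g / sum(x[keep])
  }
  mass_shares <- rbind(slow = share(slow), fast = share(fast))
  list(groups = groups, mass_shares = t(mass_shares), excluded = excluded)
}
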