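#' Write a data frame as a TSV artifact
#'
#' The package's single tabular dialect: tab-separated, header row, '.'
#' decimal point, UTF-8, no quoting or row names.
#'
#' @param df data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv_artifact <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV artifact with schema validation
#'
#' @param path input file.
#' @param required_cols column names that must be present.
#' @param nonnegative_cols numeric columns validated as >= 0; a violation is
#'   reported with its line number.
#' @return The validated data frame.
#' @export
read_tsv_artifact <- function(path, required_cols = character(0),
                              nonnegative_cols = character(0)) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(required_cols, names(df))
  if (length(missing))
    stop("malformed table ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  for (cc in intersect(nonnegative_cols, names(df))) {
    bad <- which(!is.na(df[[cc]]) & df[[cc]] < 0)
    if (length(bad))
      stop(sprintf("negative value in column '%s' of %s at line %d",
                   cc, path, bad[1] + 1L))
  }
  df
}

#' Load an omics panel from transcript/protein TSV tables
#'
#' Long format: columns `gene`, `condition`, `mu`, `replicate`, `value`.
#' An optional `detected` TSV (gene, condition, detected) supplies the
#' detection mask; by default a gene-condition pair is detected where a
#' value is present.
#'
#' @param transcript_path,protein_path paths to the two tables.
#' @param detected_path optional detection-mask table.
#' @return An `omics_panel`.
#' @export
load_omics_panel <- function(transcript_path, protein_path,
                             detected_path = NULL) {
  tr <- read_tsv_artifact(transcript_path,
                          c("gene", "condition", "mu", "replicate", "value"),
                          nonnegative_cols = "value")
  pr <- read_tsv_artifact(protein_path,
                          c("gene", "condition", "mu", "replicate", "value"),
                          nonnegative_cols = "value")
  cm <- unique(tr[, c("condition", "mu")])
  cond <- growth_conditions(cm$condition, cm$mu)
  genes <- sort(unique(tr$gene))
  reps <- max(tr$replicate)
  to_array <- function(df) {
    a <- array(NA_real_, dim = c(length(genes), nrow(cond), reps),
               dimnames = list(genes, cond$name, NULL))
    a[cbind(match(df$gene, genes), match(df$condition, cond$name),
            df$replicate)] <- df$value
    a
  }
  transcript <- to_array(tr); protein <- to_array(pr)
  if (!is.null(detected_path)) {
    dd <- read_tsv_artifact(detected_path, c("gene", "condition", "detected"))
    detected <- matrix(FALSE, length(genes), nrow(cond),
                       dimnames = list(genes, cond$name))
    detected[cbind(match(dd$gene, genes), match(dd$condition, cond$name))] <-
      as.logical(dd$detected)
  } else {
    detected <- !apply(is.na(protein), c(1, 2), all) &
      !apply(is.na(transcript), c(1, 2), all)
  }
  structure(list(genes = genes, classes = NULL, constants = NULL,
                 transcript = transcript, protein = protein,
                 detected = detected, conditions = cond),
            class = "omics_panel")
}

#' Write an omics panel to TSV tables
#'
#' @param panel an `omics_panel`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Named character vector of the written paths.
#' @export
write_omics_panel <- function(panel, dir, prefix = "omics") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  long <- function(a) {
    dn <- dimnames(a)
    idx <- which(!is.na(a), arr.ind = TRUE)
    data.frame(gene = dn[[1]][idx[, 1]],
               condition = dn[[2]][idx[, 2]],
               mu = panel$conditions$mu[match(dn[[2]][idx[, 2]],
                                              panel$conditions$name)],
               replicate = idx[, 3], value = a[idx],
               stringsAsFactors = FALSE)
  }
  paths <- c(
    transcript = file.path(dir, paste0(prefix, "_transcript.tsv")),
    protein = file.path(dir, paste0(prefix, "_protein.tsv")),
    detected = file.path(dir, paste0(prefix, "_detected.tsv")))
  write_tsv_artifact(long(panel$transcript), paths[["transcript"]])
  write_tsv_artifact(long(panel$protein), paths[["protein"]])
  det <- as.data.frame(as.table(panel$detected), stringsAsFactors = FALSE)
  names(det) <- c("gene", "condition", "detected")
  write_tsv_artifact(det, paths[["detected"]])
  paths
}

#' Write spike-in arrays to a TSV table
#' @param arrays list of `spikein_array` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spikein_arrays <- function(arrays, path) {
  rows <- lapply(arrays, function(a) {
    data.frame(condition = a$condition, mu = a$mu,
               probe = c(names(a$probe_intensities), names(a$spike_intensities)),
               kind = c(rep("gene", length(a$probe_intensities)),
                        rep("spike", length(a$spike_intensities))),
               intensity = c(unname(a$probe_intensities),
                             unname(a$spike_intensities)),
               total_rna_per_od = a$total_rna_per_od,
               stringsAsFactors = FALSE)
  })
  write_tsv_artifact(do.call(rbind, rows), path)
}

#' Read spike-in arrays from a TSV table
#' @param path file written by [write_spikein_arrays()].
#' @return List of `spikein_array` objects.
#' @export
read_spikein_arrays <- function(path) {
  df <- read_tsv_artifact(path, c("condition", "mu", "probe", "kind",
                                  "intensity", "total_rna_per_od"),
                          nonnegative_cols = "intensity")
  out <- lapply(split(df, df$condition), function(d) {
    g <- d[d$kind == "gene", ]; s <- d[d$kind == "spike", ]
    structure(list(condition = d$condition[1], mu = d$mu[1],
                   probe_intensities = stats::setNames(g$intensity, g$probe),
                   spike_intensities = stats::setNames(s$intensity, s$probe),
                   total_rna_per_od = d$total_rna_per_od[1]),
              class = "spikein_array")
  })
  out[order(vapply(out, `[[`, numeric(1), "mu"))]
}

.pipeline_stages <- c("simulate", "quantify", "efficiency", "fit", "economy",
                      "report")

#' Validate a pipeline run configuration
#'
#' A run configuration is a named list (or YAML file) with keys `stages`
#' (subset of simulate, quantify, efficiency, fit, economy, report, in
#' dependency order), `outdir`, `seed`, and optional `noise_cv`,
#' `replicates`, `gauge`, `theta_low`, `theta_high`, `n_starts`,
#' `n_genes`, `class_proportions`. Unknown keys are rejected.
#'
#' @param config named list or path to a YAML file.
#' @return The validated config list.
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  allowed <- c("stages", "outdir", "seed", "noise_cv", "replicates", "gauge",
               "theta_low", "theta_high", "n_starts", "n_genes",
               "class_proportions")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$stages) || !all(config$stages %in% .pipeline_stages))
    stop("config$stages must be a subset of: ",
         paste(.pipeline_stages, collapse = ", "))
  pos <- match(config$stages, .pipeline_stages)
  if (is.unsorted(pos))
    stop("stages out of dependency order; required order is: ",
         paste(.pipeline_stages, collapse = " -> "))
  if (is.null(config$outdir)) stop("config$outdir is required")
  if (is.null(config$seed)) stop("config$seed is required")
  defaults <- list(noise_cv = 0.05, replicates = 24, gauge = "ref_ratio",
                   theta_low = 0.1, theta_high = 10, n_starts = 5,
                   n_genes = 120, class_proportions = c(223, 698, 81) / 1002)
  for (k in names(defaults)) if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  config
}

#' Run the analysis pipeline end to end
#'
#' Executes the requested stages in order on synthetic truth: `simulate`
#' (generate all inputs), `quantify` (spike-in scaling and total mRNA),
#' `efficiency` (reporter lambda profiles), `fit` (joint inference),
#' `economy` (conservation solver scenarios), `report` (JSON summary).
#' Every output carries the seed and config echo in a manifest with file
#' checksums; a rerun with an identical config is bit-identical.
#'
#' @param config a run configuration (list or YAML path); see
#'   [validate_run_config()].
#' @return The manifest (named list), invisibly; files under
#'   `config$outdir`.
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  truth <- generator_truth(noise_cv = config$noise_cv,
                           replicates = config$replicates,
                           seed = config$seed)
  files <- character(0)
  state <- new.env(parent = emptyenv())
  need <- function(stage, obj) {
    if (is.null(state[[obj]]))
      stop("stage '", stage, "' requires upstream stage output '", obj,
           "'; add the producing stage to config$stages")
    state[[obj]]
  }
  for (stage in config$stages) {
    if (stage == "simulate") {
      state$reporter <- generate_reporter_library(truth)
      state$arrays <- generate_spikein_arrays(truth)
      state$panel <- generate_omics(truth, n_genes = config$n_genes,
                                    class_proportions = config$class_proportions)
      state$composition <- generate_rna_composition(truth)
      f1 <- file.path(outdir, "reporter_fluorescence.tsv")
      write_tsv_artifact(state$reporter$fluorescence, f1)
      f2 <- file.path(outdir, "reporter_qpcr.tsv")
      write_tsv_artifact(state$reporter$qpcr, f2)
      f3 <- file.path(outdir, "spikein_arrays.tsv")
      write_spikein_arrays(state$arrays, f3)
      f4 <- write_omics_panel(state$panel, outdir)
      f5 <- file.path(outdir, "rna_composition.tsv")
      write_tsv_artifact(state$composition, f5)
      files <- c(files, f1, f2, f3, f4, f5)
    } else if (stage == "quantify") {
      arrays <- need(stage, "arrays")
      factors <- scaling_factor(arrays)
      mrna <- total_mrna_abundance(arrays, factors)
      comp <- need(stage, "composition")
      species <- rna_species_summary(comp, B = 200, seed = config$seed)
      state$total_mrna <- mrna
      f <- file.path(outdir, "total_mrna.tsv")
      write_tsv_artifact(mrna, f)
      fj <- file.path(outdir, "quantify_summary.json")
      jsonlite::write_json(list(scaling_factors = as.list(factors),
                                mean_rrna_percent = species$mean_rrna_percent),
                           fj, auto_unbox = TRUE, digits = NA)
      files <- c(files, f, fj)
    } else if (stage == "efficiency") {
      rep_data <- need(stage, "reporter")
      strains <- unique(rep_data$fluorescence$strain)
      profs <- lapply(strains, function(s) {
        fl <- rep_data$fluorescence[rep_data$fluorescence$strain == s, ]
        qp <- rep_data$qpcr[rep_data$qpcr$strain == s, ]
        corr <- stability_correction(qp, B = 0)
        mref <- rep_data$reference_mrna
        mrna <- data.frame(condition = mref$condition,
                           abundance = corr$correct(mref$abundance, mref$mu))
        cbind(strain = s,
              efficiency_profile(fl, mrna, B = 200, seed = config$seed))
      })
      state$profiles <- do.call(rbind, profs)
      f <- file.path(outdir, "lambda_profiles.tsv")
      write_tsv_artifact(state$profiles, f)
      files <- c(files, f)
    } else if (stage == "fit") {
      profs <- need(stage, "profiles")
      data <- data.frame(id = profs$strain, condition = profs$condition,
                         mu = profs$mu, lambda = profs$lambda)
      fit <- joint_fit(data, gauge = config$gauge, seed = config$seed,
                       n_starts = config$n_starts)
      state$fit <- fit
      f <- file.path(outdir, "fit_result.json")
      jsonlite::write_json(list(
        gauge = fit$gauge,
        rfree = as.list(fit$rfree$values),
        poly_coeffs = fit$rfree$poly_coeffs,
        constants = lapply(fit$constants, function(cs)
          list(k1 = cs$k1, k2 = cs$k2)),
        residual_mse = fit$residual_mse,
        converged = fit$diagnostics$converged),
        f, auto_unbox = TRUE, digits = NA)
      files <- c(files, f)
    } else if (stage == "economy") {
      fit <- need(stage, "fit")
      k1 <- vapply(fit$constants, `[[`, numeric(1), "k1")
      pool <- transcript_pool(
        stats::setNames(rep(1, length(fit$constants)), names(fit$constants)),
        fit$constants, kp = 10)
      sol <- solve_rfree(r_tot = 2, pool)
      state$economy <- sol
      f <- file.path(outdir, "economy.json")
      jsonlite::write_json(list(r_tot = sol$r_tot, r_free = sol$r_free,
                                residual = sol$residual,
                                bound = as.list(sol$bound_per_gene)),
                           f, auto_unbox = TRUE, digits = NA)
      files <- c(files, f)
    } else if (stage == "report") {
      # summary over whatever upstream stages ran
      rep_list <- list(seed = config$seed, stages = config$stages)
      if (!is.null(state$fit))
        rep_list$rfree_fold_drop <-
          unname(state$fit$rfree$values[1] /
                 min(state$fit$rfree$values))
      if (!is.null(state$total_mrna))
        rep_list$total_mrna = as.list(stats::setNames(
          state$total_mrna$total_mrna, state$total_mrna$condition))
      f <- file.path(outdir, "report.json")
      jsonlite::write_json(rep_list, f, auto_unbox = TRUE, digits = NA)
      files <- c(files, f)
    }
  }
  files <- unname(files)
  manifest <- list(seed = config$seed,
                   config = config[setdiff(names(config), "outdir")],
                   files = stats::setNames(
                     as.list(unname(tools::md5sum(files))), basename(files)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
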