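#!/usr/bin/env Rscript
# Stage 1 — generate every synthetic input of the analysis from declared
# ground truth: the reporter TIR library (fluorescence + qPCR), spike-in
# expression arrays, RNA composition measurements and the paired
# transcriptome/proteome panel. All downstream stages read these tables.

suppressPackageStartupMessages(library(ribolim))

seed <- 20160518L
outdir <- "results/data"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

truth <- generator_truth(noise_cv = 0.05, replicates = 24, seed = seed)

lib <- generate_reporter_library(truth)
write_tsv_artifact(lib$fluorescence, file.path(outdir, "reporter_fluorescence.tsv"))
write_tsv_artifact(lib$qpcr, file.path(outdir, "reporter_qpcr.tsv"))
write_tsv_artifact(lib$reference_mrna, file.path(outdir, "reference_mrna.tsv"))

arrays <- generate_spikein_arrays(truth)
write_spikein_arrays(arrays, file.path(outdir, "spikein_arrays.tsv"))

comp <- generate_rna_composition(truth, replicates = 4, noise_cv = 0.02)
write_tsv_artifact(comp, file.path(outdir, "rna_composition.tsv"))

panel <- generate_omics(truth, n_genes = 1002,
                        class_proportions = c(223, 698, 81) / 1002)
write_omics_panel(panel, outdir)
write_tsv_artifact(
  data.frame(gene = panel$genes, class = unname(panel$classes),
             k1 = vapply(panel$constants, `[[`, numeric(1), "k1"),
             k2 = vapply(panel$constants, `[[`, numeric(1), "k2")),
  file.path(outdir, "omics_truth_constants.tsv"))

jsonlite::write_json(
  list(seed = seed, noise_cv = truth$noise_cv, replicates = truth$replicates,
       conditions = as.list(setNames(truth$conditions$mu, truth$conditions$name)),
       rfree_truth = as.list(truth$rfree_truth$values),
       rrna_fraction = truth$rrna_fraction, mrna_fraction = truth$mrna_fraction),
  file.path(outdir, "manifest.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat("Simulated inputs written to", outdir, "\n")
cat(sprintf("  reporter library: %d strains x %d conditions x %d replicates\n",
            length(truth$tir_truth), nrow(truth$conditions), truth$replicates))
cat(sprintf("  omics panel: %d genes (quota classes 223/698/81)\n",
            length(panel$genes)))
cat(sprintf("  true free-ribosome fold drop: %.2f\n",
            truth$rfree_truth$values[1] / min(truth$rfree_truth$values)))
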