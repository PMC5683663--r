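#!/usr/bin/env Rscript
# Stage 3 — reporter translation-efficiency pipeline: qPCR stability
# correction, per-strain lambda(mu) profiles and pairwise efficiency
# ratios, including the short-vs-modif1 pair whose ratio roughly doubles
# from slow to fast growth.

suppressPackageStartupMessages(library(ribolim))

indir <- "results/data"; outdir <- "results/tables"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

fluor <- read_tsv_artifact(file.path(indir, "reporter_fluorescence.tsv"),
                           c("strain", "condition", "mu", "replicate", "value"),
                           nonnegative_cols = "value")
qpcr <- read_tsv_artifact(file.path(indir, "reporter_qpcr.tsv"),
                          c("strain", "condition", "mu", "replicate", "ratio"))
mref <- read_tsv_artifact(file.path(indir, "reference_mrna.tsv"),
                          c("condition", "mu", "abundance"))

strains <- unique(fluor$strain)
profiles <- do.call(rbind, lapply(strains, function(s) {
  corr <- stability_correction(qpcr[qpcr$strain == s, ], B = 0)
  mrna <- data.frame(condition = mref$condition,
                     abundance = corr$correct(mref$abundance, mref$mu))
  cbind(strain = s,
        efficiency_profile(fluor[fluor$strain == s, ], mrna, B = 500, seed = 1))
}))
write_tsv_artifact(profiles, file.path(outdir, "lambda_profiles.tsv"))

cat("Translation-efficiency profiles (lambda = mu P / m, h^-1):\n")
for (s in strains) {
  p <- profiles[profiles$strain == s, ]
  cat(sprintf("  %-12s lambda(0.25) = %6.3f  lambda(1.70) = %6.3f  fold drop %.2f\n",
              s, p$lambda[p$mu == 0.25], p$lambda[p$mu == 1.7],
              p$lambda[p$mu == 0.25] / p$lambda[p$mu == 1.7]))
}

pair <- function(a, b) {
  er <- efficiency_ratio(fluor[fluor$strain == a, ], fluor[fluor$strain == b, ],
                         B = 500, seed = 1)
  cbind(strain_a = a, strain_b = b, er)
}
ratios <- rbind(pair("fbaA_short", "fbaA_modif1"),
                pair("fbaA_short", "fbaA_fbaA"))
write_tsv_artifact(ratios, file.path(outdir, "efficiency_ratios.tsv"))

sm <- ratios[ratios$strain_b == "fbaA_modif1", ]
cat(sprintf("\nshort/modif1 efficiency ratio: %.2f at 0.25 h^-1 -> %.2f at 1.70 h^-1 (x%.2f)\n",
            sm$ratio[sm$mu == 0.25], sm$ratio[sm$mu == 1.7],
            sm$ratio[sm$mu == 1.7] / sm$ratio[sm$mu == 0.25]))
cat("A ratio shift of ~2-fold between TIRs differing by point mutations is the\n")
cat("signature of ribosome-limited, TIR-specific translation initiation.\n")
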