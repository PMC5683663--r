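# ribolim

Growth rate-dependent translation efficiency and free-ribosome limitation
in bacteria.

## The problem

In balanced growth, a stable protein settles at `P = m λ / μ`: transcript
abundance times translation efficiency, diluted by growth. Textbook models
treat the per-transcript translation efficiency λ (proteins per mRNA per
hour) as invariant across growth rates. Measurements in *Bacillus subtilis*
contradict this: reporter efficiencies fall up to fourfold from slow
(0.25 h⁻¹) to fast (1.70 h⁻¹) growth, and different translation initiation
regions (TIRs) fall by different amounts — a regulator-free, sequence-
hard-coded mode of global regulation. `ribolim` implements the model-based
analysis behind that conclusion for anyone who wants to fit, simulate or
stress-test it: systems biologists working on bacterial resource
allocation, and synthetic biologists choosing TIRs whose output must track
(or ignore) growth rate.

## The model

Translation efficiency follows a Michaelis–Menten rate law in the free
ribosome abundance `R` (the pool of 30S initiation complexes):

    λ_i(R) = K1_i · R / (K2_i + R),         P_i = m_i λ_i / μ

with two TIR-specific constants per transcript. As growth accelerates,
total mRNA roughly doubles with μ while `R` drops; transcripts with
`K2 ≪ R` keep constant efficiency (saturated), those with `K2 ~ R` follow
the drop nonlinearly (unsaturated), and those with `K2 ≫ R` track `R`
proportionally (undersaturated). The package provides:

* `joint_fit()` / `genome_wide_fit()` — joint nonlinear least squares for
  the latent trajectory `R(μ)` and all `{K1_i, K2_i}`, with gauge fixing,
  saturation classification and threshold sensitivity;
* `simulate_three_step()` / `reduce_to_mm()` — a mechanistic three-step
  initiation model (binding, start-codon accommodation, 50S joining) and
  its exact steady-state reduction to `{K1, K2}`;
* `scaling_factor()` / `total_mrna_abundance()` / `rna_species_summary()` —
  spike-in anchored array normalization and RNA-species accounting;
* `efficiency_profile()` / `efficiency_ratio()` / `stability_correction()`
  — the reporter pipeline with qPCR mRNA-stability correction;
* `solve_rfree()` / `equilibrium_shift()` / `ribosomal_feedback_scenario()`
  — the whole-proteome ribosome-conservation solver
  `R + Σ m_i λ_i(R)/kp_i = R_tot`;
* `generator_truth()` and the `generate_*()` family — a synthetic-data
  generator emulating the full study design (8-condition growth grid,
  reporter TIR library, spike-in arrays, 1,002-gene omics panel), so the
  entire pipeline runs and is tested without external data.

## Worked example

Generate a reporter library at the study conditions (8 growth rates, 24
replicates, 5% noise) and jointly infer the free-ribosome trajectory and
the per-TIR constants:

```r
library(ribolim)

truth <- generator_truth(noise_cv = 0.05, replicates = 24, seed = 1)
lib <- generate_reporter_library(truth)
d <- data.frame(id = lib$fluorescence$strain,
                condition = lib$fluorescence$condition,
                mu = lib$fluorescence$mu, P = lib$fluorescence$value,
                m = lib$reference_mrna$abundance[match(lib$fluorescence$condition,
                                                       lib$reference_mrna$condition)])
fit <- joint_fit(d, gauge = "ref_ratio", ref_id = "hs_fbaA",
                 n_starts = 10, seed = 1)
fit$rfree
#> Free-ribosome trajectory (gauge: ref_ratio)
#>   condition   mu     rfree
#> 1       M9P 0.25 0.7074445
#> 2      M9SE 0.40 0.5463044
#> 3         S 0.60 0.3995250
#> 4       M9G 0.75 0.3211308
#> 5       M9M 0.80 0.2979838
#> 6        TS 0.90 0.2604615
#> 7        CH 1.20 0.1707580
#> 8       CHG 1.70 0.1594439
round(fit$rfree$values[1] / min(fit$rfree$values), 2)
#> 4.44
sapply(fit$constants[c("fbaA_short", "fbaA_fbaA", "fbaA_modif1")],
       function(cs) round(c(K1 = cs$k1, K2 = cs$k2), 3))
#>    fbaA_short fbaA_fbaA fbaA_modif1
#> K1      1.023     2.262       7.482
#> K2      0.315     2.069       7.053
```

The inferred free-ribosome pool drops 4.4-fold from the slowest to the
fastest medium, with the sharp decline before 1.2 h⁻¹ and a plateau after.
The short-TIR construct's half-saturation constant comes back at `K2 ≈
0.3` — inside the spanned `R` range, so its efficiency falls only twofold
— while the modif1 TIR's `K2 ≈ 7` sits far above it (a ~22-fold spread
here, truth 25-fold), so its efficiency tracks the full free-ribosome
drop. All scales are relative to the gauge `K1/K2 = 1` for the `hs_fbaA`
reference construct.

The `analysis/` directory holds the full narrative workflow as numbered
drivers (`01_simulate.R` … `05_ribosome_economy.R`): simulation, spike-in
quantification, reporter efficiencies, joint and genome-wide inference,
and the ribosome-economy scenarios. Each writes its tables under
`results/` and prints what it found.

## Further reading

The methods vignette (`vignettes/ribolim-methods.Rmd`) documents the model
assumptions, the two exact non-identifiabilities of the Michaelis–Menten
family and the conventions that resolve them, the synthetic generator's
defaults and their rationale, estimator choices, and known limitations.
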