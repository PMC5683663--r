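---
title: "Modelling growth rate-dependent translation efficiency with ribolim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling growth rate-dependent translation efficiency with ribolim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

At balanced exponential growth, a stable protein encoded by transcript $i$
accumulates to

$$P_i = \frac{m_i\,\lambda_i}{\mu + \gamma_i},$$

where $m_i$ is the transcript abundance, $\mu$ the growth rate (h$^{-1}$),
$\gamma_i$ the protein degradation rate (0 for stable reporters such as
GFPmut3) and $\lambda_i$ the translation efficiency — proteins made per
mRNA per hour. The classical view treats $\lambda_i$ as a constant. The
model implemented here instead makes it a Michaelis–Menten function of the
*free ribosome* abundance $R$ — the pool of 30S initiation complexes
(30S·IF1·IF2·IF3·GTP·fMet-tRNA) available to engage an mRNA:

$$\lambda_i(R) = \frac{K_{1i}\,R}{K_{2i} + R}.$$

$K_{1i}$ (h$^{-1}$) is the saturated efficiency of the transcript's
translation initiation region (TIR); $K_{2i}$ (in $R$ units) is its
half-saturation point. When the cell grows faster, total mRNA rises roughly
in proportion to $\mu$ while the free pool $R$ falls; transcripts then sort
into three regimes relative to the spanned $R$ range: **saturated**
($K_2 \ll R$, efficiency flat), **unsaturated** ($K_2 \sim R$,
Michaelis–Menten behaviour) and **undersaturated** ($K_2 \gg R$, efficiency
proportional to $R$, so only the slope $K_1/K_2$ is meaningful).

### Mechanistic grounding: the three-step initiation scheme

`simulate_three_step()` integrates the mass-action kinetics of a
knowledge-based initiation scheme: reversible binding of the free 30S
complex to the message ($k_b$, $k_{-b}$), reversible accommodation onto the
start codon ($k_a$, $k_{-a}$), irreversible 50S joining ($k_t$), then
first-order completion of elongation at $k_p$, the population-averaged
inverse elongation time. With $R$ and free 50S clamped as condition-level
boundary species, the steady state of the bound complexes is linear and can
be solved exactly; `reduce_to_mm()` implements the resulting aggregation

$$K_1 = \frac{k_t S\,k_a}{k_{-a} + k_t S + k_a},\qquad
  K_2 = \frac{k_{-b}\,(k_{-a} + k_t S) + k_a\,k_t S}
             {k_b\,(k_{-a} + k_t S + k_a)},$$

with $S$ the clamped 50S abundance. The reduction is exact at steady state,
which the test suite verifies against the ODE integrator to better than 1%
over three decades of $R$. The 50S abundance is growth rate-dependent in
principle; it is folded into the per-condition constants here rather than
modelled separately, which is flagged as a simplification rather than a
claim. Per-codon ribosome traffic and stochastic initiation are outside the
model's scope; only the `standard` assembly scenario is implemented.

## Identifiability: one gauge was not enough

The fitted model $\lambda_{ic} = K_{1i} R_c/(K_{2i} + R_c)$ is famously
scale-free: $(R, K_2) \mapsto (cR, cK_2)$ changes nothing. The package
resolves this **gauge** by either anchoring $R = 1$ at the slowest
condition (`anchor_slowest`, the genome-wide convention) or scaling a
reference construct's $K_1/K_2$ to 1 (`ref_ratio`, the reporter-library
convention).

Working in reciprocal coordinates exposes a second exact invariance. With
$x = 1/R$, $\alpha_i = 1/K_{1i}$, $\beta_i = K_{2i}/K_{1i}$,

$$\frac{1}{\lambda_{ic}} = \alpha_i + \beta_i\,x_c,$$

so the affine substitution $x_c \to x_c + t$, $\alpha_i \to \alpha_i -
\beta_i t$ preserves *every* prediction for any $t$ that keeps all
$\alpha_i \ge 0$. No amount of data distinguishes points along this
direction; it is as real as the scale gauge, though bounded (at one end
the most undersaturated transcript becomes exactly linear, $\alpha = 0$;
at the other some $R_c$ diverges). `joint_fit()` therefore applies a second
convention after optimization, as an exact objective-preserving transform:
the largest fitted $K_2$ is placed at the finite cap
$10^4 \times \max_c R_c$, i.e. the most undersaturated transcript is
reported as effectively linear and its identified quantity is $K_1/K_2$.
Because the transform moves a transcript with $K_2 \gg R$ by design, its
effect on unsaturated and saturated constants is of order
$K_2^{(i)}/K_2^{(\max)}$ — a few percent at most in the panels generated
here, and negligible for the reporter library, whose linear constructs are
generated genuinely linear. Classification thresholds are defined relative
to the $R$ range, so class labels are invariant under both conventions.

## The joint fitting procedure

`joint_fit()` minimizes

$$\sum_i \sum_c w_{ic}\,\bigl(\log \lambda^{obs}_{ic} -
  \log \tfrac{K_{1i} R_c}{K_{2i}+R_c}\bigr)^2$$

by alternating exact separable solves: for each transcript, $\log K_1$ is
closed-form given $K_2$ and the profile objective is a 1-D search over
$\log K_2$; for each condition, a 1-D search over $\log R_c$. Each half-step
is an exact coordinate minimization, so the objective descends
monotonically (asserted per iteration in the tests); iteration stops at a
relative change below $10^{-10}$. Twenty seeded multistarts are the default
(five in genome-wide mode, where the problem is larger but much more
strongly constrained); ties are broken by the lowest objective, then the
smallest $K_2$ norm. Residuals are taken on the log scale because all the
assays here are multiplicative (positive abundances, array intensities,
fluorescence); a linear-scale option (`scale = "linear"`) is provided since
the choice shifts $K_2$ estimates slightly and neither is canonical.
Weights are inverse replicate variances of $\log \lambda$, floored at
10% of their mean so no single cell dominates.

Positivity is enforced by log-parameterization throughout, and $K_2$ is
capped at $10^4 \times \max R$ so undersaturated fits stay finite; that
class is reported through $K_1/K_2$.

## What the synthetic generator emulates

The generator defines the study conditions; its defaults are fixed once:

* **Condition grid** — the eight media spanning $\mu = 0.25$–$1.70$
  h$^{-1}$ (M9P to CHG).
* **Free-ribosome truth** — a monotone cubic through declared anchors,
  dropping sharply from 0.70 at $\mu = 0.25$ to 0.17 at 1.2 h$^{-1}$ and
  plateauing at 0.16 by 1.7 h$^{-1}$. The anchors encode a total drop of
  4.4-fold: the reported behaviour is "at least fourfold", while the
  quoted $R$ range (0.7 down to 0.2) brackets the half-saturation constant
  0.3 of the short-TIR construct; 0.70 → 0.16 honours both statements.
* **Reporter library** — six TIR constructs: three with finite $K_2$
  (0.3, 2.0 and 7.5 — the last 25-fold above the first, reproducing the
  reported $K_2$ spread between the modif1 and short TIRs) and three
  effectively linear reference-promoter constructs, consistent with how
  the fitted library is reported. Fluorescence replicates default to 24
  (12 technical × 2 biological); qPCR stability ratios default to 8
  replicates per medium.
* **Noise** — multiplicative log-normal with unit mean; CV defaults to 5%.
  The assays' true noise magnitudes are not published, so the CV is a
  calibration knob, not a claim. At CV = 0 every observable equals its
  closed-form value exactly, which the round-trip tests exploit.
* **Spike-in arrays** — total RNA per OD proportional to $\mu$, a constant
  mRNA fraction of total RNA, ten spike transcripts added in identical
  amounts to every array, per-array library scale applied to all probes,
  noise last.
* **Omics panel** — 1,002 genes by default, assigned to the three
  saturation classes by deterministic quota in the reported proportions
  (223/698/81). Class-conditional $K_2$ ranges (saturated:
  $\le 0.01 \min R$; unsaturated: $[\min R/3,\,3 \max R]$; undersaturated:
  $\ge 100 \max R$) are an invention needed to make classes well separated
  in truth; they are documented as such.

What the generator does **not** emulate: probe-sequence and dye effects,
image-level array artifacts, peptide-level proteomics, condition-specific
post-transcriptional regulation, and any correlation structure between
$K_1$ and $K_2$ (the panel draws them independently). Tests passing on
these data therefore validate the estimators under the stated noise model,
not the biology of any real dataset.

## Estimator choices in the quantification pipeline

* **Spike-in scaling factor** — per array, the reciprocal of the median
  (across the ten spikes) ratio to the cross-array geometric-mean
  reference, then mean-normalized to 1. The median tolerates a failed
  probe; the geometric mean suits multiplicative intensities. The original
  regression-based procedure is not published in detail, so this robust
  estimator is a declared substitute with the same invariances (exactly
  cancels any per-array global rescale).
* **Total mRNA** — scale-corrected summed mRNA signal (the mRNA fraction
  of the hybridized aliquot) times total RNA per OD, anchored to 1.0 at
  the $\mu = 0.4$ condition. The anchor is explicit configuration, not an
  implicit "slowest present" rule.
* **Efficiency ratios** — per condition, least squares through the origin
  over all replicate pairs: $\hat r = \sum P_a P_b / \sum P_b^2$ after
  mRNA-stability correction. Whether the original minimization pooled
  conditions is unstated; per-condition was chosen and is flagged. Note
  the estimator's small variance bias ($\hat r = 1/(1+\mathrm{CV}^2(n-1)/n)$
  on identical inputs), visible only below the assay noise floor.
* **Trend fits** — polynomial degrees follow the conventions of the
  source figures (degree 1 for total RNA and total rRNA fraction, 2 for
  rRNA sub-species, 3 for fluorescence, qPCR and $R(\mu)$ smoothing) and
  are configuration-exposed. Confidence bands are percentile bootstraps
  over replicates, $B = 1000$ by default, seeded; the original CI method
  is unstated.
* **Two-group partition** — a transcript is enriched when its fast/slow
  ratio strictly exceeds the total-mRNA ratio; ties go to "depleted"
  (the boundary is undefined in the source).
* **Class thresholds** — saturated below $0.1 \min R$, undersaturated
  above $10 \max R$. Only "$\ll$" and "$\gg$" are stated; the counts'
  sensitivity to these thresholds is emitted with every genome-wide fit.

## The ribosome economy

`solve_rfree()` solves the whole-proteome conservation relation

$$R + \sum_i \frac{m_i\,\lambda_i(R)}{k_{p,i}} = R_{tot}.$$

Each term counts ribosomes in transit as initiation flux times mean
elongation time; a translating 70S counts as one unit against $R_{tot}$
(30S-centred bookkeeping). Whether the original relation also counts
initiation-complex occupancy is unknown; an optional occupancy term is
exposed but off by default, isolated behind `bound_ribosomes()`. The left
side is strictly increasing in $R$ with $f(0) = -R_{tot} < 0$ and
$f(R_{tot}) \ge 0$, so bracketed bisection on $[0, R_{tot}]$ finds the
unique root to $|f| < 10^{-12} R_{tot}$; a damped fixed-point iteration
serves as an independent cross-check in the tests. `equilibrium_shift()`
and `ribosomal_feedback_scenario()` wrap the solver into the two
mechanism experiments: a growth-rate step where extra message titration
outweighs extra ribosomes, and the question of whether enriching only
near-saturated ribosomal messages (2.5-fold, with $R_{tot}$ doubling) can
reproduce a fourfold free-pool drop — it cannot, because saturated
messages add only a bounded, $R$-independent titration offset.

## Numerical choices and degenerate inputs

* ODE integration: `deSolve::lsoda` at `rtol 1e-12`/`atol 1e-14`,
  steady state declared when the relative derivative norm falls below
  $10^{-10}$; non-convergence within the horizon raises an error with the
  residual derivative norm. Negative integrator states beyond round-off
  abort.
* $K_2 = 0$ with $R = 0$ is a domain error (0/0); $m = 0$ transcripts are
  excluded from ratio tests and reported rather than propagated.
* `joint_fit` requires every id in at least three conditions, and warns
  (rather than fails) when all ids fit saturated, where the scale is
  genuinely unidentified.
* Bisection tolerance, convergence criteria and the multistart count are
  all arguments with the defaults above.

## Problem sizes

The shipped tests and drivers use the study-scale designs: 6 reporter
constructs × 8 conditions × 24 replicates for the library fit, a
1,002-gene panel for genome-wide classification, 4 arrays-worth of RNA
composition replicates, $B = 200$–$1000$ bootstrap draws, and 400
simulations for the coverage study — sizes at which every analysis
completes in seconds to a couple of minutes on a single core.

## Known limitations

Identifiability is resolved by convention, not by data: absolute $R$ and
absolute $K_2$ scales are meaningful only within a stated gauge, and
undersaturated $K_2$ values are reported as ratios for that reason. The
fitted constants absorb any condition-specific post-transcriptional
effects. Class counts depend on the declared thresholds (a sensitivity
sweep accompanies every fit) and, at realistic noise, transcripts near the
undersaturated boundary are the hardest to pin down — their $K_2$
estimates carry sampling errors of the same order as typical acceptance
tolerances. Bayesian uncertainty quantification and formal identifiability
analysis are out of scope.
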