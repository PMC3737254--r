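---
title: "Methods: segregation analysis of latent Adiposity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segregation analysis of latent Adiposity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adiposeg)
```

## The model

`adiposeg` tests whether adiposity segregates in families with a history
of type 2 diabetes (T2DM) in the way a *dominantly expressed major gene*
would predict, and inverts the observed segregation into risk-allele
frequencies.

The phenotype is not a raw measurement but a latent factor. Six body
measurements — height, waist and hip circumference, and DXA lean, bone
and fat mass — are log-transformed (masses scale with volume, lengths
with a single dimension, so logs make their relationships linear),
standardized, and decomposed by maximum-likelihood factor analysis into
two orthogonal factors. After varimax rotation the loading pattern is
interpretable: one factor loads the skeletal measures (*Frame*), the
other fat mass and the circumferences (*Adiposity*). Bartlett's
weighted-least-squares scores give per-individual factor values in SD
units, unbiased for the latent factors under the model.

Gender and age effects are removed by taking residuals from the additive
linear model `trait ~ gender + age tertile` (no interaction; the additive
form is used because interactions are absent in the data this analysis
targets, and residuals are invariant to factor coding). Age tertiles are
cut at the pooled-sample 33.3%/66.7% quantiles; lower-closed intervals,
ties to the lower tertile. Pooling the tertiles across FH groups matches
the pooled-decile convention used downstream.

The adjusted Adiposity scores are then binned by *deciles of the pooled
sample*, and three quantities are computed:

* **Relative risks.** Per decile, `RR_i = (n_i+/N+) / (n_i-/N-)` with a
  95% CI from the normal approximation on the log scale,
  `SE = sqrt(1/n_i+ - 1/N+ + 1/n_i- - 1/N-)`.
* **The bimodal fit.** The FH+ bin densities at the decile midpoints are
  fitted by least squares to the equal-variance two-component normal
  density `(1-α)·φ(x; m₁, s) + α·φ(x; m₁+d₂, s)`, with `α ∈ [0,1]` and
  `d₂ ≥ 0` enforced by bounded optimization. `m₁` is the lower-mode mean,
  `d₂` the separation between modes, `s` the common within-mode SD and
  `α` the fraction under the upper mode — all in SD units of the adjusted
  score.
* **Heritability.** With the trait in SD units, the within-mode variance
  is the non-genetic residual, so `h² = 1 − s²` on the adjusted scale;
  multiplying by `1 − R²(gender+age)` expresses it on the unadjusted
  scale.

Finally the phenotypic fractions become allele frequencies under a
dominant bi-allelic model in Hardy–Weinberg equilibrium: carriers (Aa,
aa) express the phenotype, so `α = 2pq + q²` and `q = 1 − √(1−α)`. Three
population-genetic steps deserve explicit statement because they carry
the analysis's key assumptions:

1. `α_FH− = α_FH+ / RR₈`: the FH− group's own mixture is too weak to fit,
   so its upper-mode fraction is anchored to the relative risk in the 8th
   decile, where upper-mode enrichment concentrates. This assumes RR₈
   faithfully reflects the relative upper-mode occupancy of the groups.
2. `q_T2DM = 2·q_FH+ − q_FH−`: offspring (FH+) inherit one allele from an
   affected parent and one from a spouse; treating the FH− group as the
   spouse pool and assuming random mating, the offspring frequency is the
   mean of the two parental pools.
3. Family history is read as a purely genetic signal (shared-environment
   effects on body composition are assumed negligible, and
   gene–environment interactions saturated).

Every derived parameter receives a percentile confidence interval from a
stratified bootstrap: individuals are resampled with replacement within
FH group at the original group sizes, and by default the *entire*
pipeline — factor extraction included — is re-run on each draw, so
factor-model uncertainty propagates honestly. `freeze_factors = TRUE`
instead resamples the precomputed adjusted scores (faster, and closer to
a reading in which the factor structure is treated as fixed).

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `n_boot` | 1000 | draws | reference analysis's draw count |
| `rr_decile` | 8 | decile | where upper-mode enrichment concentrates |
| `n_starts` | 20 | starts | the 4-parameter SSE surface is multimodal |
| `decile_scope` | `"pooled"` | — | FH+ densities binned on pooled-sample edges |
| `s` floor | 0.01 | SD | prevents degenerate density spikes |
| uniqueness floor | 0.005 | — | Heywood-case clamp (warned) |

`decile_scope = "fh_plus"` re-derives the decile edges from the FH+
subsample alone; the pooled default reflects our reading that a single
set of full-sample deciles underlies both the RR profile and the density
fit, and the flag exposes the alternative.

## The synthetic-cohort generator

The raw participant data behind this design are not publicly deposited,
so `simulate_cohort()` generates cohorts with exactly the structure the
analysis assumes, giving every downstream stage a known ground truth:

* genotypes drawn under Hardy–Weinberg equilibrium with `q = 0.09` (FH−,
  n = 122) and `q = 0.36` (FH+, n = 80);
* latent Adiposity `= m₁ + d₂·1[carrier] + slope·(tertile − 2) + N(0, s)`
  with `d₂ = 0.93`, `s = 0.30`, an age slope of 0.3 SD per tertile, and
  `m₁` chosen so the pooled latent mean is 0;
* latent Frame `= ±gender_effect/2 + N(0, 0.5)` with a male–female
  difference of 1.75 SD (≈ the observed Frame contrast), gender
  Bernoulli(0.6 female), ages uniform on [20, 70];
* six log-measurements
  `mean_j + scale_j·(λ_j1·Frame + λ_j2·Adiposity + √ψ_j·ε_j)`,
  exponentiated to natural units. The default loading pattern puts
  height/lean/bone ≈ 0.9 on Frame and fat ≈ 0.95, waist/hip ≈ 0.85 on
  Adiposity, with uniquenesses equal to one minus the communalities.

All draws come from a single RNG stream in documented order (gender, age,
genotype, Frame noise, Adiposity noise, measurement errors), so a seed
fully determines a cohort. The genotype column is emitted as ground truth
but never read by the pipeline.

**A scale subtlety.** The forward model feeds the latent factors into the
measurement equation as-is. With the paper-like defaults the pooled
latent Adiposity SD is ≈ 0.59 (within-mode 0.30, carrier mixture, age
trend), not 1. Since the analysis standardizes the observed measures, the
fitted factor is the *standardized* latent: recovered scores are the
latent rescaled to ~unit SD, so score-scale estimates of `d₂` and `s` are
the generating values divided by ≈ 0.59 (≈ 1.6 and ≈ 0.5), while `α`, the
relative risks, heritability's interpretation and all allele frequencies
are scale-invariant. Ground-truth recovery tests therefore target `α` and
the allele-frequency chain end-to-end, and `d₂`/`s` directly at the
mixture level.

What the generator does **not** emulate: measurement error correlated
across instruments, non-normal within-mode tails, ethnic admixture,
assortative mating, missing data, or any selection applied at
recruitment. Passing tests show the *method* recovers the truth under its
own assumptions, not that real cohorts satisfy them.

## Numerical choices

* **Bimodal fit.** Unweighted least squares on the ten binned densities
  (the simplest reading of fitting "bin densities to the model");
  L-BFGS-B with bounds `α ∈ [0,1]`, `d₂ ≥ 0`, `s ≥ 0.01`; 20 starts
  crossing `α ∈ {0.2, 0.5, 0.8}`, `d₂ ∈ {0.3, 0.9, 1.5}` and moment-based
  `m₁`, `s`; convergence controls `factr = 100`, `pgtol = 1e-12`,
  finite-difference steps `1e-7`. A fit is flagged *degenerate* when
  `d₂ < 0.05`, `α` is within 0.02 of a boundary, or the fitted mixture
  density has a single local maximum — the model then describes an
  effectively unimodal distribution and the "two modes" reading does not
  apply, though the parameter chain is still reported.
* **Varimax.** For two factors the rotation is a single planar angle
  whose Kaiser-normalized criterion is a sinusoid in 4θ, so the optimum
  is computed analytically (the generic iterative routine can stall at a
  saddle for symmetric patterns); more factors delegate to
  `stats::varimax`. Tests verify the analytic angle against an exhaustive
  grid search.
* **Binning.** Decile bins are half-open `[e_i, e_{i+1})` with the last
  bin closed; tied decile edges are an error naming the quantile (a trait
  with heavy ties cannot be decile-profiled); in resampled data, values
  falling outside the edge range clamp to the outer bins.
* **Zero cells.** A decile empty in one group gets the Haldane–Anscombe
  0.5 correction applied to that decile's four counts only and is
  flagged; empty in both groups (impossible for pooled deciles of the
  observed data, possible in principle for exotic inputs) yields a
  flagged `NA` rather than an error.
* **Clamps.** `α_FH−` and `q_T2DM` are clamped to [0, 1] with a warning
  rather than an error, because bootstrap draws legitimately cross the
  boundaries; inside the bootstrap these warnings are suppressed and the
  draw is kept.
* **Standardization** uses the sample-SD (n−1) convention; standardizing
  explicitly before factor analysis is equivalent to the correlation-
  matrix route for loadings and documented here for scores.
* **Failed bootstrap draws** (optimizer failure or non-finite parameters)
  are dropped and counted; a summary with more than 20% failures is
  flagged unreliable.

## Design choices where the design was open

* The two formula steps of the allele chain (`α₋ = α₊/RR₈`,
  `q_T2DM = 2q₊ − q₋`) are reconstructions: each is the unique simple
  form consistent with the downstream values the analysis is known to
  produce, and both are called out above as assumption-bearing.
* Tertiles and deciles are computed on the pooled sample, not per gender
  or per FH group; the per-group alternative for the density fit is
  exposed via `decile_scope`.
* The bootstrap defaults to re-fitting the factor model per draw; the
  frozen-score variant is an explicit option rather than the default
  because the honest propagation of factor uncertainty is the more
  conservative choice.
* `m₁` has no natural published value; the generator defaults it so the
  pooled latent mean is zero, mirroring a centred score scale.

## Test problem sizes

The suite exercises convergence properties at sizes chosen to make the
asymptotic claims sharp while keeping the full run quick: correlation-
structure recovery at n = 10⁵, Bartlett unbiasedness at n = 10⁴,
mixture-parameter recovery over 200 replicate FH+ samples of n = 80
(matching the study's group size), and bootstrap coverage with 200 draws
over 20 replicate cohorts.

## Limitations

At n = 202 the decile-density fit is noisy: single realizations can
return broad, effectively unimodal solutions (flagged), and the
bootstrap intervals on `α` and the allele frequencies are wide — this
mirrors the wide intervals of the motivating analysis and is a property
of the design, not of the implementation. The HWE inversion is exactly
as strong as its assumptions: dominance, random mating, a spouse-pool
FH− group and an RR that tracks upper-mode occupancy. The package fits a
bimodal model; it deliberately does not test for bimodality (no dip
test), model unequal variances or more than two modes, or model
recessive/additive inheritance.
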