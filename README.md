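# adiposeg

Segregation analysis of a latent **Adiposity** phenotype in cohorts
stratified by first-degree family history of type 2 diabetes (FH+ / FH−).

## The problem

Obesity is strongly co-transmitted with type 2 diabetes (T2DM), yet common
variants explain only a small fraction of its heritability. One way to ask
whether *rare variants with large effects* drive diabetes-associated
obesity is a classical segregation argument: if a dominantly expressed
major gene raises adiposity, the adiposity distribution in relatives of
T2DM patients (FH+) should be a *mixture of two modes*, with the fraction
under the upper mode fixed by Mendelian arithmetic rather than drifting
continuously as a polygenic model would predict.

`adiposeg` implements that argument end to end for six routinely measured
body variables (height, waist and hip circumference, DXA lean, bone and
fat mass):

1. **Factor extraction** — maximum-likelihood factor analysis of the six
   log-transformed, standardized measures; varimax rotation; Bartlett
   scores. Two orthogonal factors emerge: *Frame* (skeletal size) and
   *Adiposity* (fat stores).
2. **Covariate adjustment** — residuals from the additive model
   `trait ~ gender + age tertile`.
3. **Segregation statistics** — the adjusted Adiposity scores are binned
   by deciles of the pooled sample; per-decile relative risks
   RR_i = p_i(FH+)/p_i(FH−) with log-normal CIs; the FH+ bin densities are
   fitted to an equal-variance bimodal normal model
   `y = (1−α)·φ(x; m₁, s) + α·φ(x; m₁+d₂, s)`
   by bounded multistart L-BFGS-B (α ∈ [0,1], d₂ ≥ 0).
4. **Heritability** — `h² = 1 − s²` on the adjusted scale, rescaled by the
   covariate R² for the unadjusted trait.
5. **Hardy–Weinberg inversion** — under dominant expression,
   α = 2pq + q², so `q = 1 − √(1−α)`; the FH− upper-mode fraction comes
   from α₊/RR₈; the allele frequency in unobserved T2DM-affected relatives
   from the spouse-pool relation `q_T2DM = 2q₊ − q₋`.
6. **Bootstrap** — every parameter gets a percentile CI from a stratified
   bootstrap over individuals (resampling within FH group at the original
   sizes), re-running the whole pipeline per draw.

Because the original participant-level data are not deposited, the package
ships a **synthetic-cohort generator** (`simulate_cohort()`) with exactly
the statistical structure the analysis assumes — a dominant bi-allelic
genotype under Hardy–Weinberg equilibrium shifting latent Adiposity by
`d₂` SD in carriers, a gendered Frame factor, and a two-factor measurement
model on the log scale — so every stage is testable against known ground
truth.

## Worked example

```r
library(adiposeg)

cohort <- simulate_cohort(sim_config(), seed = 3)  # 122 FH- + 80 FH+
fit <- adiposeg(cohort, n_boot = 1000, seed = 4)
fit
#> Segregation analysis of latent Adiposity by family history of T2DM
#>   N = 122 FH- + 80 FH+
#>   Factors explain 76% of standardized variance
#>   Bimodal fit (FH+): d2 = 1.64 SD, s = 0.63, alpha = 0.51
#>   RR (decile 8) = 3.56; heritability 60% adjusted, 55% unadjusted
#>   Risk allele q: 0.07 (FH-), 0.30 (FH+), 0.52 (T2DM)
#>   Bootstrap: 1000 draws (0 failed)
```

Reading the output: about half of the simulated FH+ group (α = 0.51) sits
under an upper Adiposity mode separated by 1.6 SD from the lower one; FH+
individuals are 3.6 times more likely than FH− to fall in the 8th decile
of pooled adjusted Adiposity; inverting the dominant Hardy–Weinberg
relation gives risk-allele frequencies of 0.07 in FH−, 0.30 in FH+, and
0.52 in the unobserved affected relatives. The generating cohort used
q = 0.09 (FH−) and q = 0.36 (FH+), so the chain recovers the truth within
the (wide, n = 202) sampling error shown by `summary(fit)`:

```r
summary(fit)
#>       parameter  point median  ci_lo ci_hi
#>              d2  1.639  1.676  1.212 2.113
#>   alpha_fh_plus  0.509  0.538  0.252 0.757
#>      q_fh_minus  0.074  0.149  0.044 0.635
#>       q_fh_plus  0.300  0.320  0.135 0.507
#>          q_t2dm  0.525  0.467  0.002 0.859
#>   ...
```

`coef(fit)` returns the parameter vector, `plot(fit)` draws the FH+
density with the fitted mixture and the decile RR profile,
`simulate(fit)` generates new cohorts from the fitted parameters, and
`write_report(fit, "report.json")` serializes everything.

The population-genetics arithmetic is exposed directly:

```r
q_from_alpha(0.59)                  # 0.3597 — dominant-model inversion
allele_estimates(0.59, rr_8 = 3.6)  # full FH-/FH+/T2DM chain
heritability(0.30, 0.12)            # h2: 91% adjusted, 80% unadjusted
```

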