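---
title: "Triangulating alcohol's effect on brain iron: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triangulating alcohol's effect on brain iron}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irontri)
```

# The inference problem

Whether moderate alcohol consumption causes iron accumulation in the brain
cannot be settled by a single analysis. Observational regressions of brain
susceptibility (χ, a quantitative-susceptibility-mapping marker of regional
iron, in parts per billion) on weekly alcohol intake are confounded by
everything that travels with drinking — age, sex, smoking, deprivation,
diet, genotype. Mendelian randomization (MR) replaces the measured exposure
with genetically predicted exposure, trading confounding for a different
set of assumptions (instrument relevance, exchangeability, exclusion
restriction). Mediation analysis asks a mechanistic question the other two
cannot: how much of the alcohol–brain iron association travels through
systemic iron stores, proxied by liver iron (mg/g)? Where all three designs
point the same way, a causal claim is more credible than under any one of
them; this package implements that triangulation as a tested, reusable
chain, exercised end to end on synthetic data with known ground truth.

# The observational stage

Phenotypes are quantile normalized before modelling with the rank-based
inverse normal transform `qnorm((r - 3/8)/(n + 1/4))` — the Blom offset,
with midranks for ties. The choice of offset matters little at the sample
sizes involved (all common offsets agree to a few parts in a thousand for
n in the tens of thousands); Blom is the conventional default and is what
`inverse_normal_transform()` implements. A fully tied vector transforms to
zeros with a warning rather than an error, because degenerate phenotype
columns occur in practice and should not kill a pipeline.

Models are ordinary least squares on complete cases. Two-sided p-values
use the t distribution with residual degrees of freedom; no
robust/sandwich standard errors are applied, matching plain adjusted
regression practice for these phenotypes. Weekly consumption (UK units;
1 unit = 8 g ethanol) is categorized into quintiles — octiles for a
sensitivity analysis — among *current drinkers only*, with never and
previous drinkers retained as their own categories and the lowest quintile
of drinkers as the reference (using abstainers as reference understates
alcohol-related risk). For continuous models the standardized exposure is
used; categorization is applied to the raw units. Multiple-testing
correction (Bonferroni and Benjamini–Hochberg FDR via `p.adjust`) is
applied separately per analysis family, i.e. one family for the
alcohol × susceptibility models and one for susceptibility × cognition
style models; the family is always exactly the vector handed to
`adjust_pvalues()`.

The genetic iron risk score is the dosage-weighted sum over rs1800562 and
rs1799945 (HFE) and rs855791 (TMPRSS6), the three common European variants
with the largest serum-iron effects; weights are the published per-allele
associations supplied by the caller, so updated GWAS weights drop in
without a code change.

# Two-sample Mendelian randomization

Instruments are variants associated with the exposure at genome-wide
significance (p < 5 × 10⁻⁸). Harmonization expresses both studies' effects
on the same allele: nominal swaps flip the outcome beta and complement the
frequency; strand flips are recognised by base complement. Palindromic
(A/T, G/C) variants cannot be resolved from allele codes; they are aligned
by effect-allele frequency when both frequencies fall outside the
ambiguity window — default (0.30, 0.70), configurable — and excluded as
`palindromic-ambiguous` otherwise, including when either frequency is
missing. No proxies are looked up and no LD operations are performed;
instruments are treated as independent.

With harmonized per-variant effects (β_Xj, β_Yj) and outcome standard
errors se_Yj, the estimators are:

* **IVW (multiplicative random effects).**
  β̂ = Σ w_j β_Xj β_Yj / Σ w_j β_Xj², w_j = 1/se_Yj² — weighted regression
  through the origin. The fixed-effect SE 1/√(Σ w_j β_Xj²) is inflated by
  max(1, √(Q/(J−1))); flooring at 1 means heterogeneity can only widen,
  never narrow, the interval. A single variant degrades gracefully to the
  Wald ratio, flagged in the result.
* **MR-Egger.** The same weighted regression with a free intercept, fitted
  after re-orienting all variants so β_X ≥ 0 (without that orientation the
  intercept has no directional-pleiotropy interpretation). The slope is
  consistent under InSIDE — pleiotropic effects independent of instrument
  strength; the intercept estimates the average directional pleiotropic
  effect. SEs are inflated by max(1, √(Q_egger/(J−2))).
* **Weighted median.** Wald ratios β_Yj/β_Xj sorted, each assigned the
  percentile (S_j − w_j/2)/S_J of its cumulative inverse-variance weight,
  linearly interpolated at the 50th percentile. Consistent when valid
  instruments carry more than half the weight.
* **Mode-based.** The mode of the inverse-variance-weighted Gaussian
  kernel density of the Wald ratios; consistent when the largest group of
  instruments sharing a causal estimate is the valid group. The bandwidth
  is `bandwidth_factor` × the modified Silverman rule
  0.9·min(sd, mad)·J^(−1/5) computed on the ratios themselves (the robust
  variant of Silverman's rule conventional for this estimator), with
  `bandwidth_factor = 1` by default; the factor is exposed because the
  estimate's sensitivity to bandwidth is itself a diagnostic.

Wald-ratio standard errors use the first-order delta method se_Yj/|β_Xj|
with no weak-instrument (NOME) correction; the second-order term is
negligible whenever the exposure GWAS is much larger than the outcome
GWAS, the regime this design targets, and the simplification is standard.
Median and mode SEs come from a parametric bootstrap resampling
(β_Xj, β_Yj) from their sampling distributions — 5,000 seeded resamples by
default, with `n_boot = 0` available to skip the bootstrap when only point
estimates are needed (as in the recovery simulations). All estimator
p-values use the normal reference distribution, consistent with the
field's standard implementations; Egger with very few variants is
anti-conservative under this choice, which is one reason `mr_egger()`
refuses J < 3.

Diagnostics: Cochran's Q = Σ(β_Yj − β̂ β_Xj)²/se_Yj² on J−1 degrees of
freedom; per-variant instrument F = (β_X/se_X)² with F < 10 flagged weak
(weak-instrument bias in two-sample MR points toward the null); and
analytic power Φ(|effect|·√(n·R²) − z_{1−α/2}) for a standardized
continuous outcome — the normal approximation used by the standard online
MR power calculator. At the design point n = 29,579, R² = 0.003,
α = 0.05, this gives 65.4% power for a 0.25 SD effect, which the test
suite pins to ±0.0005.

# Causal mediation

`mediate()` fits the mediator model M ~ X + Z and the outcome model
Y ~ X + M + Z by OLS on complete cases and decomposes the total effect by
product of coefficients: indirect = a·b, direct = c′, total = c′ + a·b,
proportion mediated = indirect/total. In this linear, no-interaction
structural model the product-of-coefficients quantities coincide with the
counterfactual natural direct and indirect effects, so the simple
decomposition *is* the causal one under the usual no-unmeasured-confounding
assumptions (exposure–outcome, exposure–mediator, mediator–outcome). No
exposure–mediator interaction is included by default because the target
analysis reports single path coefficients; the decomposition identity
total = direct + indirect then holds to numerical precision on every fit,
and the package asserts it in tests at 1e-10.

Confidence intervals are percentile bootstrap over individuals, 1,000
resamples by default, seeded; bias-corrected variants were deliberately
not used because the target analysis specifies plain nonparametric
bootstrap CIs, and the percentile method keeps the p-value definition
(2·min(fraction of draws ≤ 0, ≥ 0), capped at 1) coherent with the
interval. When |total| < 1e-12 the proportion mediated is reported as `NA`
with a warning rather than an unstable ratio. The proportion's CI is
derived from the same bootstrap draws as the effect CIs, not a separate
run.

A degenerate case worth knowing: with an *exactly* noise-free mediator the
outcome design is collinear (M is then a linear function of X and Z) and b
is unidentified. The zero-noise validation fixtures therefore keep a
vanishing but nonzero mediator residual (SD 1e-4), which is the
identifiable limit of the zero-noise structural model.

# What the synthetic data emulate — and what they do not

`simulate_cohort()` draws a linear structural model: standardized exposure
X ~ N(0,1) among current drinkers (never/previous drinkers get X = 0 and a
category label, matching complete-case category + quantity coding); raw
weekly units are the lognormal back-transform matched to mean 17.7, SD
15.9 units; mediator M = 1.2 + aX + γᵀZ + ε (liver iron, mg/g); each
outcome Y = c′X + bM + γᵀZ + ε (standardized regional susceptibility).
Defaults are the study conditions of the motivating analysis: n = 20,729
(6,936 for the liver subsample used in mediation), 2.7% never drinkers,
a = 0.05 mg/g per SD, b = 0.44 SD per mg/g, c′ = 0.047 — implying a true
proportion mediated of ≈32%. The previous-drinker fraction is not printed
in the source material; 3.5% was chosen once as realistic for a UK cohort
of this age structure. Iron-risk dosages are Binomial(2, f) with
f = (0.07, 0.14, 0.45) for rs1800562, rs1799945, rs855791. Covariates are
independent standard normals reported in natural units (age 54.8 ± 7.4
years, BMI 26.5 ± 4.0 kg/m², and so on) — a deliberate simplification:
real covariates are correlated, so passing tests here demonstrates correct
estimation under the stated model, not robustness to realistic covariate
structure. Selection effects, reporting error in self-reported intake, and
imaging confounds (site, motion, head position) are likewise not
simulated; the latter enter the model surface only as generic covariate
columns.

`simulate_summary_stats()` draws J independent variants with effect-allele
frequencies Uniform(0.05, 0.95), a configurable fraction (default 10%)
palindromic; true exposure effects have half-normal magnitudes
(effect-allele oriented trait-increasing, the convention under which
directional pleiotropy is directional) rescaled so Σ 2f(1−f)β² equals the
configured R²; outcome effects are β·β_X + α_j; estimated effects add
noise with SE 1/√(2f(1−f)n). Pleiotropy modes: `none`, `balanced` (zero
mean), `directional` (nonzero mean, independent of instrument strength —
InSIDE holds), and `inside_violating` (correlation 0.5 with instrument
strength). The outcome table's allele presentation is scrambled per
variant — 30% nominal swaps, 20% strand flips for non-palindromic
variants, 30% strand flips for palindromic ones — so harmonization is
exercised on every run, and the truth record keeps the aligned values for
verification. Defaults mirror the alcohol-instrument setting: J = 91,
exposure GWAS n = 941,280, outcome GWAS n = 29,579, R² = 0.003, causal
effect 0.25. Linkage disequilibrium between instruments is deliberately
absent (instruments are modelled as independent sentinel variants), so
clumping is out of scope by construction.

# Simulation sizes and numerical choices

Validation scenarios were fixed once, from the statistical requirements of
each property, and the suite runs them at these sizes:

* Estimator recovery (all four estimators, no pleiotropy): J = 50,
  β = 0.2, exposure n = 10⁷, outcome n = 10⁶, 200 replicates. "Large n"
  here means large enough that weak-instrument attenuation
  (≈ R²/(R² + J/n_exposure)) is an order of magnitude below the 0.02 bias
  budget; at the default R² = 0.003 with both samples at 10⁵ the
  attenuation alone is ≈1.4% of the estimate, which is why the
  all-estimator recovery scenario uses larger samples, while the IVW-only
  recovery check runs at outcome n = 10⁵ with the default exposure GWAS
  size.
* Directional pleiotropy under InSIDE: mean pleiotropic effect 0.002
  (≈ a 0.1–0.15 bias on the IVW scale given the instrument-strength
  distribution), SD 0.002 — large enough that IVW visibly fails
  (bias > 0.05) while Egger's debiasing is measurable against the 0.02
  budget.
* 40% invalid instruments: two generated sets concatenated, with the
  total instrument R² split 60/40 so the *weight* fraction — what the
  weighted median's guarantee is about — matches the invalid fraction;
  both samples at 10⁷ because the median's robustness is an asymptotic
  statement and at smaller n the estimate sits on the shoulder of the
  valid cluster.
* Q calibration: J = 20, exposure n = 10⁸ (so exposure-side noise, which
  the Q statistic ignores, is negligible and the null is correctly
  specified), 1,000 replicates; the empirical size must fall in
  [0.03, 0.07].
* Mediation coverage: n = 5,000 per cohort, 1,000 bootstrap resamples,
  20 replicates, requiring ≥ 18/20 intervals to cover the true
  proportion.

Other numerical choices: the multiplicative random-effects inflation and
the Egger inflation are floored at 1; Egger orientation breaks the
β_X = 0 tie toward +1; `wald_ratios()` excludes β_X = 0 variants with a
warning rather than dividing by zero; the weighted-median interpolation
clamps to the extreme ratios outside the percentile range; the mode falls
back to the median of ratios when the bandwidth degenerates to zero
(identical ratios); and every stochastic routine takes an explicit seed
and restores the caller's RNG state, so a fixed master seed reproduces an
entire pipeline run bit for bit (`run_pipeline()` expands one master seed
into per-stage seeds).

# Known limitations

The package reproduces the *statistical machinery* of the triangulation
design, not its data: image processing (QSM reconstruction, T2* fitting,
liver MRI), derivation of weekly units from beverage questionnaires, LD
clumping for instrument selection, and GWAS execution are all upstream of
the interfaces implemented here. Egger p-values use the normal reference
and are anti-conservative at small J. The power formula is a normal
approximation for continuous outcomes and does not cover binary outcomes.
The mediation machinery assumes linearity and no exposure–mediator
interaction; an interaction would require the counterfactual definitions
rather than the product of coefficients, and is out of scope. The
generator's covariates are independent, so confounding structure in tests
is simpler than in any real cohort — parameter-recovery results here
validate the estimators, not the untestable causal assumptions they rest
on.
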