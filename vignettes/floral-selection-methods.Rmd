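---
title: "Methods: selection analysis and path models for floral traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selection analysis and path models for floral traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(florsel)
```

`florsel` implements the statistics of a phenotypic-selection study on
flower colour in *Silene littorea*: trait and fitness construction,
Lande–Arnold selection coefficients, variance-comparison tests, and a
recursive linear path-analysis engine with model enumeration, trimming and
bootstrap inference. This vignette records the models, their assumptions,
and the design decisions behind the implementation.

## Colour index

Anthocyanin concentration in petals and calyces is scored as the **R:G
ratio**: the mean pixel value of the red channel divided by that of the
green channel over a selected region of a linearised RGB image. We use the
ratio of channel means, not the mean of per-pixel ratios; per-pixel ratios
explode on dark pixels, while channel means are stable. Images are first
put on a common linear scale by a two-point calibration per channel
(`calibrate_channels()`), the linear map that sends the measured values of
two neutral gray standards to their expected reflectances. The expected
reflectances are configuration inputs, not package constants — they depend
on the chart and the linearisation workflow. Calibrated values below zero
are clamped to zero and counted in a warning. No specular-highlight
filtering is applied; if the photographic protocol requires it, mask the
highlights before computing the ratio.

## Fitness components

Per plant (`fitness_components()`):

* **fruit-set** = fruits / total flowers; **seed-set** = ripe / (ripe +
  aborted) per sampled fruit, averaged over the up-to-three sampled
  fruits; sampled fruits with zero ovules are excluded from the means
  (not scored as zero) and reported.
* **total female fitness** = mean ripe seeds per fruit × total fruit
  production. Female and hermaphrodite flowers both count.
* **male fitness**: the pollen-removal assay counts grains in ten 10-µl
  subsamples of a 1.5-ml suspension in which one or two anthers were
  washed. Scaling: mean subsample count × (suspension / subsample volume)
  = grains in the washed anthers; ÷ anthers counted; × anthers per flower
  = undispersed grains per flower. Dispersed grains per flower = population
  mean pollen production − undispersed, clamped at zero with a flag
  (sampling noise can push the undispersed estimate above the mean
  production); × hermaphrodite flowers = total male fitness. The species
  bears ten stamens, so `anthers_per_flower` defaults to 10, but the
  anther-to-flower scaling is exposed as a parameter because it is an
  assumption, not a measurement. Plants without assay data are excluded
  from male-fitness analyses.
* **ovary predation** = chewed ovaries / total flowers (one ovary per
  flower), a proportion in [0, 1].

## Selection analysis

All coefficients follow the Lande–Arnold regression framework on
**relative fitness** *w* (absolute fitness over the population mean;
mean 1 by construction) and **variance-standardized traits** *z*
(zero mean, unit sample SD). Relativisation and standardization are always
done *within* population, never pooled: pooling would confound
between-population mean differences with selection. Sample (n−1)
denominators are used throughout, which makes *S′* equal the OLS slope on
a unit-variance predictor.

* opportunity *I* = var(*w*) (`selection_opportunity()`), compared across
  populations with the Brown–Forsythe test on plant-level relative
  fitness pooled over populations;
* differentials *S′* = cov(*zⱼ*, *w*) with p-values from the univariate
  regression of *w* on *zⱼ* — the univariate-regression test is a
  documented assumption, since a covariance has no canonical test;
* gradients *β′* from one multiple regression of *w* on all standardized
  traits, with classical SEs. When the in-sample trait correlation matrix
  is the identity, *β′* = *S′* exactly (tested).

Missing data are handled complete-case *per analysis*: differentials use
pairwise-complete cases per trait, gradients listwise-complete cases, so
sample sizes legitimately differ across cells of the output table. No
multiple-testing correction is applied. Rank-deficient designs abort with
the offending columns named rather than silently dropping traits.

The univariate machinery (`welch_t()` from raw data *or* printed
summaries, `wilcoxon_rank_sum()` with exact enumeration up to combined
n = 12 and tie-corrected normal approximation beyond, `brown_forsythe_test()`
as a one-way ANOVA on absolute deviations from the group median,
`pearson_corr()`, `cv_percent()`) is deliberately reproducible from
summary statistics, so published worked examples can be checked without
raw data.

## Path analysis

A path model (`path_model()`) is a DAG of observed variables plus optional
residual covariances between endogenous variables (the double-headed
arrows drawn for unresolved, non-causal associations). With coefficients
B and residual/exogenous (co)variances Ψ, the implied covariance is
Σ(θ) = (I−B)⁻¹Ψ(I−B)⁻ᵀ. Fitting is covariance-structure-only (means
saturated and ignored), by minimising the normal-theory discrepancy

F(θ) = ln|Σ(θ)| − ln|S| + tr(S Σ(θ)⁻¹) − p,

with χ² statistic T = (N−1)·F̂ (the Jöreskog–Sörbom multiplier; a
convention, and every within-run comparison is invariant to it).
Numerical choices: residual and exogenous variances are parameterized on
the log scale to enforce positivity; BFGS with per-equation OLS warm
starts; non-positive-definite trial Σ is rejected with a large objective
value; convergence is reported with the terminal gradient norm. For
recursive models *without* residual covariances, per-equation OLS is the
exact ML solution (the likelihood factorises along the topological order);
`engine = "ols"` uses that closed form, the optimizer route is the
default, and the two are tested to agree to 1e-6.

Information criteria are on the χ²-plus-penalty scale, AIC = T + 2t and
BIC = T + t·ln N. These are rank-equivalent, for fixed data, to
likelihood-based criteria; absolute values are not comparable across
software conventions, only orderings are meaningful.

**Enumeration.** `enumerate_near_saturated()` generates, over all
topological orderings consistent with the exogenous set, the saturated
recursive model minus 1–2 edges (df 1–2). Different orderings of
unconnected variables can imply identical covariance structures, so
candidates are deduplicated *numerically*: two candidates merge when
their fitted implied covariances coincide on fixed random probe matrices
(equivalent models project any covariance identically; inequivalent ones
differ for generic probes). Each returned class keeps its provenance
(ordering, removed edges) and class size. The construction in the original
study reportedly produced 102 models per population; our enumeration is a
principled reconstruction of "near-saturated models differing in the order
of unconnected variables" and its class count is not forced to match.
`rank_candidates()` scores all classes via the per-equation factorisation
of F (memoised by effect/parent-set), exactly matching `fit_path()`.

**Trimming.** `trim_model()` iteratively removes the non-significant path
with the smallest |standardized coefficient|, refits, and records the
nested Δχ² test against the baseline; it stops when all remaining paths
are significant or a removal is rejected, and returns the visited model
with the lowest AIC (ties by BIC). Note a structural consequence: for a
truly null path, the Δχ² is below the AIC acceptance margin of 2 in only
~84% of samples, so the final AIC re-selection occasionally reinstates a
baseline whose superfluous edge the trimming sequence had already
eliminated; the `steps` table records both facts.

**Inference.** `bootstrap_path()` resamples plants with replacement,
refits per replicate (failures dropped and counted; >5% warns, >50%
errors), and reports SD-based SEs, percentile intervals and
normal-approximation Z/p — both are reported because the study's Z-based
p-values imply the normal approximation, while percentile intervals are
the distribution-free alternative. `indirect_effects()` multiplies
unstandardized coefficients along every directed path, sums paths
excluding the direct edge, and propagates the bootstrap replicates through
the same products. Total female fitness can be divided by 1,000 before
fitting (`rescale`), the study's device for taming its dominant variance;
standardized coefficients are invariant to it.

## The synthetic populations

The study's raw plant data are not deposited, so the generator is the
test bed. `population_preset()` encodes two population presets:
`"barra-like"` and `"melide-like"`, carrying the published trait means and
SDs, the standardized coefficients of the generating causal structure
(corolla colour → calyx colour 0.36 / 0, corolla colour → flower number
0.30 / −0.37, flowers → ovary predation 0.58 / 0.76, ovary predation →
seeds −0.45 / 0, flowers → seeds 1.03 / 0.82), display–flower-number
correlations 0.49 / 0.83, and pollen production 21,711.33 / 18,192.3
grains per flower.

`simulate_population()` draws, in topological order: corolla colour from
a truncated normal (lower bound R:G = 1 — a ratio below 1 would mean
greener-than-red petals); each endogenous variable as a linear function
of its *observed* parents plus Gaussian residual; counts rounded and
clamped at zero; ovary predation additionally capped at the flower count
(one ovary per flower); floral display conditionally on flower number to
achieve the preset correlation, with a minimum of one open flower. Fruit
and per-fruit seed counts are constructed to be consistent with the
generated seed total, so the fitness estimators approximately invert the
generator. Pollen dispersal fractions are Beta-distributed with moments
matched to dispersed-per-flower / production; Beta avoids the clamping
bias a truncated normal would add at the many near-complete-dispersal
plants.

Rounding, clamping and truncation all distort observed moments and
attenuate observed regression coefficients relative to the latent
Gaussian scale — with ~15–20% of latent seed counts censored at zero,
naively plumbing the published SDs through produces standardized
coefficients visibly below their targets. The presets therefore store
*calibrated* latent parameters, derived by `calibrate_preset()`: a damped
stochastic fixed-point iteration (default 40 iterations at n = 4e5,
damping 0.4, plus a mean/SD polish stage with coefficients frozen,
tail-averaged to remove Monte-Carlo wobble) that adjusts latent means,
residual SDs, coefficients and the latent display correlation until the
*observed* quantities match the preset targets. The stored constants are
reproducible by re-running the function.

What the generator does **not** emulate: pollinator behaviour, spatial or
temporal structure, multivariate non-normality beyond what
rounding/censoring induces, and any dependence of the independently drawn
traits (corolla area, calyx length, ovules) on the causal block. Passing
recovery tests on these data therefore shows the estimators are correct
under the generating assumptions, not that the field data meet them. One
known artefact: censoring the seed count at zero makes its regression on
correlated predictors mildly nonlinear, which induces a small spurious
partial association (of order 0.1 standardized in the melide-like preset)
between ovary predation and seeds even though the generating coefficient
is zero; model-selection experiments therefore use the barra-like preset,
whose generating paths are all non-zero.

## Problem sizes and tolerances

The test suite runs recovery at n = 5,000 (three-SE moment checks, ±0.05
on standardized coefficients, ±0.03 on the display–flower correlation),
model-selection and trimming experiments over 100 replicates of n = 5,000
(scored through the memoised closed-form ranker), a 10⁶-draw simulation
oracle for the implied-covariance algebra, and exhaustive permutation
oracles for the rank-sum test up to combined n = 12. Bootstrap agreement
with classical OLS SEs is checked at n = 1,000 with B = 1,000. These sizes
keep every Monte-Carlo tolerance comfortably above its sampling noise.

## Known limitations

* Estimation assumes multivariate normality for inference; the χ² and
  classical SEs are asymptotic. The bootstrap is the primary inference
  route for non-normal data, mirroring the study.
* Non-recursive (cyclic) systems, latent variables, robust/WLS estimators
  and FIML missing-data handling are out of scope.
* The colour module handles linear arrays and thin PNG/TIFF reading only;
  camera-RAW decoding and colour-space transforms beyond the two-point
  calibration belong upstream.
* Exact Wilcoxon enumeration is combinatorial and capped at combined
  n = 12; beyond that the tie-corrected normal approximation is used.
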