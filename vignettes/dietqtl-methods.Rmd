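---
title: "dietqtl: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dietqtl: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `dietqtl`, the defaults
and tunable parameters, the numerical choices, and what the synthetic-data
generator does and does not emulate. It states no empirical result beyond
what the test suite and `scripts/acceptance.R` themselves compute.

## The gene–environment mixed model

The phenotype at one analysis age is a vector `Y` (grams) over N mice.
Environments are binary columns `Z_e`: one per generation cohort across the
whole age range, plus one per diet group at and after the intervention age
(180 days in the motivating study design, giving E = 12 before and E = 17
after with 12 generations and 5 diets). Genotypes `G_v` are
founder-of-origin probability 8-vectors at typed markers (unit L1 norm per
mouse and marker) or expected allele dosages in `[0, 2]` at imputed
variants. The model places fixed effects on the intercept and environment
memberships, independent normal priors on per-variant additive effects
(variance `rho^2 / V`) and on per-variant-per-environment interaction
effects (variance `Omega_ee / V`, with Omega diagonal — interaction effect
sizes are assumed uncorrelated between environments), and heteroscedastic
noise whose variance for mouse n is the sum of `sigma_e^2` over the
environments n belongs to. Marginally,

    Y ~ N(X alpha, Lambda),
    Lambda = Theta + rho^2 K + sum_e Omega_ee (K o Z_e Z_e^T),

with the kinship `K_mn = (1/V) sum_v G_mv' G_nv`. An
environment-independent noise term is not included, since it is not
identifiable alongside the per-environment terms when every mouse belongs
to at least one environment column. EMMA is the nested special case
`Omega = 0` with a single noise variance.

Phenotypes are not standardized, so all effect sizes and variance
components are in grams (and grams squared) and comparable across ages.

### Fitting

Fixed effects are profiled out analytically by GLS at each parameter
value, and the profile likelihood is maximized over
`(sigma_1^2 .. sigma_E^2, rho^2, Omega_11 .. Omega_EE)` by L-BFGS-B with
analytic gradients

    dL/d theta_j = -tr(Lambda^-1 A_j)/2 + Y' P A_j P Y / 2,

where `A_j` is `I_Ze`, `K`, or `K o Z_e Z_e'` and `P` is the GLS
projection. Components are constrained non-negative by default
(`constrained = FALSE` relaxes the genetic components, at the cost of a
possible non-positive-definite covariance near the boundary, which the
optimizer treats as a rejected step). Defaults: 3 starts (one
moment-based, the rest seeded random rescalings), projected-gradient
tolerance 1e-6, 500 iterations; every linear-algebra step goes through a
Cholesky factor of `Lambda`. Fits at different ages are independent — no
factorization is shared, since `Lambda` changes with the per-age
components. EMMA fits rotate the data by the eigenvectors of `K` once, so
each likelihood evaluation is diagonal; the eigendecomposition can be
reused across fits that share a kinship matrix (`eig =`).

The non-negativity constraint matters for interpretation but introduces a
small downward median bias at low true PVE (estimates that would be
negative pile up at zero and the sampling distribution is asymmetric).
This is visible in the protocol recovery study at a target of 0.2 and is
a property of the constrained estimator, not of the optimizer.

### PVE

The proportion of variance explained by genetics is the model-implied
expectation of the genetic share of the sample variance. Both the total
and the environment-conditional decompositions are exact linear functions
of the variance components (trace and double-sum functionals of `K`,
restricted through Hadamard products with `Z_e Z_e'` for the conditional
version), so `pve_total()` / `pve_env()` are closed-form, and their
standard error is obtained by the delta method: the observed information
of the components is the numerically differentiated analytic gradient
(central differences, relative step 1e-4), and the PVE gradient is
analytic. A nonparametric bootstrap over mice is available behind
`method = "bootstrap"` for small problems. Reported PVE is clipped to
`[0, 1]` only when the components were constrained non-negative; the raw
ratio is always kept alongside.

The kinship–covariance diagnostic (`kinship_covariance_diagnostic()`)
scores every within-diet animal pair by the product of the two animals'
deviations from the diet-mean weight — a pairwise covariance — and
compares high-kinship (> 0.2) and low-kinship pairs by a two-sided
Mann–Whitney U test (normal approximation with tie correction), reporting
`AUC = U / (n1 n2)`. The pair statistic is this package's concrete choice
of "covariance in body weight between a pair"; other definitions
(e.g. rank-based) would be equally defensible.

## Trend filtering of weight series

Raw weekly weights are smoothed per mouse by l1 trend filtering:

    minimize 0.5 * sum_i (y_i - x_i)^2 + lambda * sum_i |(D x)_i|

where `D` takes second differences along the age grid (divided differences
scaled by the mean spacing, so the penalty's kernel is exactly the lines in
age even when measurements are irregularly spaced). The solution is
piecewise linear; its knots are where the slope changes, and growth rate
(grams/day) is the exact slope between consecutive fitted points. We
penalize second differences — not first — because a piecewise-*linear*
trend is the target; first differences would produce piecewise-constant
fits.

The solver is ADMM with the quadratic step pre-factorized (sparse
Cholesky of `I + rho D'D`, `rho = lambda`), soft-thresholding for the
penalty step, and tolerance 1e-8 on the max-norm primal and dual
residuals. Tests verify the two limits (`lambda = 0` interpolates;
`lambda -> infinity` gives the OLS line) and compare the attained
objective against the strong-duality bound of an independently solved box
QP dual.

`select_lambda()` chooses the penalty by held-out prediction: 10% of each
mouse's interior ages (at least one held out, at least three kept) are
predicted by linear interpolation of the fit to the rest, squared errors
are pooled across mice, and the minimizing `lambda` from a 30-point
logarithmic grid spanning 1e-2 to 1e4 is returned; the holdout is
seed-controlled. Fraction and grid are package choices — the procedure is
"minimize held-out error over a grid" with no canonical fraction — and
are overridable.

## Association scans

The additive statistic for variant s is the natural-log likelihood ratio
`Phi_a` between models with and without focal fixed effects, under
leave-one-chromosome-out kinship (the focal chromosome's markers are
excluded from `K` so the focal variant's signal is not absorbed by the
polygenic term). Founder-probability variants enter through a sum-to-zero
contrast over the 8 founders (7 columns, keeping the intercept
identifiable); dosages as one column. The interaction statistic `Phi_i`
adds genotype-by-diet fixed effects (coded against the first diet column
as reference) on top of a null that retains the additive focal effect, so
it responds only to between-diet differences in the variant effect.
`LOD = Phi / ln 10`.

By default the variance components are estimated once per (age,
chromosome) under the no-focal-variant model and held fixed while focal
effects are profiled across that chromosome's variants — the statistic is
then half the drop in the GLS residual quadratic form, computed by
whitening once per chromosome and projecting per variant. Re-maximizing
all parameters per variant (`refit = TRUE`) implements the likelihood
ratio literally and is available for small runs and oracle tests; the
fixed-components approximation is standard practice in mixed-model scans
and is what makes genome-wide-by-age scans feasible. Variants whose focal
columns vanish after projection on the base design (monomorphic in the
sample) are flagged and given `Phi = 0`.

### Permutation p-values

Significance is assessed by permuting phenotype rows and recomputing the
statistic under the fixed fitted covariance. The default permutation is
unrestricted (any order equally likely), matching the motivating
procedure; a `within =` factor restricts shuffling to design cells
(e.g. generation or diet) for users who prefer a restricted
randomization. The sequential rule draws permutations until `C_stop = 10`
of them reach the observed statistic or the budget `M_max` is exhausted;
ties count as exceedances. On early stopping the p-value is drawn
uniformly from `[C/M, (C+1)/(M+1)]`; on budget exhaustion it is
`(C+1)/(M+1)`.

Two calibration caveats are inherent and documented rather than patched.
First, permutation p-values are exactly valid only under exchangeability;
when the fitted covariance carries substantial polygenic structure,
unrestricted permutation is an approximation (the motivation for using
permutations at all is that the parametric assumptions are themselves
approximate). Second, stopping at 10 exceedances caps the resolution of
non-significant p-values at roughly 1/10 near p = 1 — the support
concentrates on `{10/M}` — so the full distribution of null p-values is
uniform in its body and tail but coarse at the top. Calibration tests
therefore check rejection rates at practically relevant levels; a
Kolmogorov–Smirnov test against the uniform over the whole unit interval
will reject any sequential procedure of this kind by construction.

### Significance thresholds

The number of effective tests is estimated from the LD structure:
per-chromosome correlation matrices of the genotyped markers are
eigendecomposed, eigenvalues pooled genome-wide, and `M_eff` is the
smallest number of top eigenvalues explaining the target fraction of the
total variance — 90% for the significant tier and 99.5% for the stringent
tier. Thresholds are `alpha / M_eff` with `alpha = 0.05` (the family-wise
level is a package choice; the motivating analysis reports the resulting
thresholds without stating alpha). The suggestive tier is ten times the
significant threshold and, following the motivating analysis, is applied
to interaction tests only.

## Fine-mapping by founder allele pattern

Untyped variants are imputed from the founder mosaic: founder
probabilities at the variant position are linearly interpolated (in
physical position) between the flanking typed markers, and the expected
dosage is the probability-weighted founder allele count. Linear
interpolation is the package's choice; any monotone interpolation would
be nearly identical at realistic marker densities, and the imputation is
exact whenever the mosaic is constant across the flanking interval.

Each significant variant's FAP is the set of founders carrying its minor
allele (the side with fewer founders; a 4/4 tie is labeled by the side
containing the first founder in the canonical order AJ, B6, 129, NOD,
NZO, CAST, PWK, WSB). Variants with a heterozygous founder call are
excluded from FAP assignment — founder strains are inbred, so a
heterozygous call indicates a genotyping problem. Variants are grouped by
FAP (a partition, by construction), each group scored by its best member
LOD, and groups ranked by that score with ties broken by member count and
label. Annotation overlap uses 0-based half-open coordinates everywhere
internally; GFF input is shifted at the boundary, BED is native, and a
variant at position p hits `[start, end)` iff `start <= p < end`.

## Nonlinearity of effect trends

Per-age effect estimates and their standard errors, treated as known,
give a weighted regression of effect size on age. The null model is
linear, the alternative cubic; the statistic is the drop in weighted
residual sum of squares (twice the log likelihood ratio under the normal
sampling model) referred to chi-squared with 2 degrees of freedom. Age is
affinely rescaled to `[-1, 1]` before constructing the polynomial basis —
a pure conditioning measure that leaves the statistic unchanged. The
tiered significance cutoffs are fixed at 1e-4 (founder effects at
diet-independent loci; 112 tests with 14 loci) and 1e-5
(founder-by-diet effects at diet-dependent loci; 760 tests with 19 loci).
Both cutoffs are stricter than 0.05 divided by the corresponding test
counts (4.5e-4 and 6.6e-5), i.e. conservative, and are applied verbatim.
Diet-dependent nonlinearity (deviation of intermediate-restriction
effects from the average of the flanking diets) is reported descriptively
only; no formal statistic is defined for it here.

## The synthetic DO generator

The generator exists so that every stage is testable without external
data. Per mouse and chromosome, the founder-of-origin sequence is a
first-order Markov chain over the 8 founders with per-marker switch
probability 0.05 (desk scale: 2 chromosomes x 250 markers; both
configurable), giving one-hot founder probabilities with local linkage.
Founder alleles are Bernoulli(0.5) per founder and marker; dosages follow
from the carried founder. Phenotypes are drawn from the zero-mean
multivariate normal implied by the model covariance via its Cholesky
factor. To hit a target per-environment PVE exactly, the shared polygenic
variance is set to zero and each interaction variance is solved in closed
form from the conditional decomposition (the inversion of targets into
components is under-determined in general; concentrating the genetic
variance in the interaction terms is the convention used here, and a
shared-variance mode remains available through `variance_components()`
directly). The protocol grid is target PVE in environment one over
{0.2, 0.5, 0.8}, environment two over {0.05, ..., 0.95}, at 1:1 and 4:1
allocation — 114 settings, 50 replicates each, noise variances fixed at 1.

What the generator does not emulate: diploid heterozygous mosaics (each
simulated genome is one founder per locus, like an inbred mosaic), the
empirical DO kinship spectrum, linkage disequilibrium between founder
alleles, genotyping error, and survival dropout. Passing tests on this
generator therefore demonstrate correctness of the algebra and estimators
under the stated model, and qualitative behaviors (EMMA's underestimation
of total PVE under environment asymmetry, minority-environment bias at
4:1, FAP recovery of injected signals) — not calibration on real DO data.

## Problem sizes and budgets in the shipped tests

The test suite and acceptance script use desk-scale sizes chosen so the
whole suite runs in minutes: N = 500 with 50 replicates per setting for
the protocol recovery study, N = 400 with 100 replicates for injected-QTL
fine-mapping recovery, 1000 null variants at `M_max = 1e4` for
permutation calibration, 1e5 Monte-Carlo draws at N = 40 for the
decomposition oracle, and 1000 replicates for nonlinearity type-I error.
These sizes are statements about the tests, not limits of the
implementation; all entry points accept full-scale inputs.

## Known limitations

- Omega is diagonal; covariation of interaction effects between
  environments is not modeled.
- The diet-level effect coding reports per-diet effects against the first
  diet column as reference; a sum-to-zero diet coding would change the
  individual coefficients but not the interaction statistic.
- The delta-method PVE standard error treats the fitted fixed effects as
  fixed and is unreliable when a component sits on the non-negativity
  boundary (the bootstrap alternative is preferable there).
- Sequential permutation p-values are coarse above ~0.9 by construction.
- The survival-bias check in the motivating design is supported as a data
  filter (restrict to mice alive at the final age and refit), not as a
  correction model.
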