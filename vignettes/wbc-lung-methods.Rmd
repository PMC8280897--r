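---
title: "Methods: WBC differentials, lung function, and two-sample MR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: WBC differentials, lung function, and two-sample MR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wbclung)
```

# Scope and model

`wbclung` implements the two arms of a blood-count / lung-function study.

The **observational arm** models spirometric lung function (FVC or FEV1, in
mL) for subject $i$ in one cohort as

$$y_i = \alpha + \beta\, x_i + \gamma' z_i + \varepsilon_i,$$

where $x_i$ is one WBC count (10^9 cells/L; eosinophils and basophils on
the log10 scale because their distributions are right-skewed) and $z_i$ the
covariates: age, sex, race (only in cohorts where race varies), height,
smoking, alcohol use, exercise. $\beta$ is the quantity of interest, in mL
per 10^9 cells/L (or per log10 unit). Per-cohort estimates are pooled by
inverse-variance meta-analysis; subtypes passing the single-marker screen
(p < .05) go through LASSO selection with unpenalized covariates and a
joint multiple-marker model that mutually adjusts the correlated subtypes.

The **genetic arm** takes harmonized per-SNP summary statistics — exposure
effects on a WBC count and outcome effects on lung function — and estimates
the causal effect by IVW, with MR-Egger and MR-PRESSO probing the
horizontal-pleiotropy assumptions.

# The synthetic-data generator

All inputs can be generated with known ground truth, which is what every
calibration and recovery test in the package uses.

**Cohorts.** WBC subtype counts are drawn from a multivariate Gaussian on
the log scale and exponentiated: a lognormal copula that yields positive,
right-skewed counts and an interpretable log-scale correlation matrix.
Total WBC is *defined* as the sum of the generated subtypes, so the
subtype-sum identity holds exactly for every subject. Outcomes are linear
in the configured covariate/exposure effects plus correlated Gaussian
residuals (FVC and FEV1 share a measurement occasion; residual correlation
defaults to 0.95). Subjects whose residual pair would violate
`fvc >= fev1 >= 0` are redrawn rather than clipped, as are any
non-positive counts (at most 100 attempts, then an error) — clipping would
silently distort the configured means. One global seed expands into named
substreams (covariates, counts, noise, survey), so adding a generated field
does not shift the draws of the others.

The bundled profiles (`cohort_profile()`) emulate three published study
populations: a US national survey (5-part differential, multi-level race,
stratified weighted design), an occupational cohort reporting a 3-part
differential (neutrophils, lymphocytes, intermediate cells), and a large
retirement cohort. Their ages, heights, category prevalences, WBC means
and outcome means follow the published cohort descriptions. Two
reconciliations were needed, both decided a priori:

* Published tables give eosinophil/basophil *medians* with 5th/95th
  percentiles; the profiles convert them to lognormal means
  ($\mu \exp(\sigma^2/2)$ with $\sigma$ fitted from the percentiles).
* The published subtype means do not add exactly to the published total
  WBC mean (rounding, median-vs-mean). Because the generator defines the
  total as the subtype sum, all subtype means are rescaled proportionally
  (a 1–2% adjustment) so the expected total matches the published total.
* Profile intercepts are back-computed so that the expected FVC/FEV1 equal
  the published cohort means given the configured effects.

Published tables report design-based SEs, not SDs, for the survey cohort,
so its age/height SDs are plausible values rather than derived ones.

What the generator does **not** emulate: linkage disequilibrium or
genotype-level structure (the two-sample generator produces already
harmonized, independent instruments), measurement error in spirometry
beyond additive Gaussian noise, informative missingness (generated tables
are complete), and non-linear dose–response. Passing tests therefore
demonstrate correctness of the estimators under their own assumptions, not
robustness to the messiness of real cohort data.

**Two-sample summary statistics.** Per SNP $j$, a true exposure effect
$\beta_{Xj}$ is drawn uniform in magnitude with random sign (mimicking a
harmonized table's mixed allele coding); the observed exposure effect adds
$N(0, se_X)$ noise. The outcome effect is
$\beta_{Yj} = \theta\,\beta_{Xj} + \mathrm{sign}(\beta_{Xj})\,\alpha_j + e_j$
with $\alpha_j$ the direct (pleiotropic) effect and
$e_j \sim N(0, se_Y)$. Direct effects are defined on the
exposure-increasing allele — the orientation MR-Egger uses — so
directional pleiotropy with mean $\delta$ is recoverable as an Egger
intercept of $\delta$; defining it on the arbitrary reported allele would
average the direction away. Planted outliers add `outlier_magnitude` to
$\alpha_j$ and are recorded in a truth sidecar.

# Estimators and numerical choices

**Outlier exclusion.** Mean and SD of total WBC are computed once on the
full sample and rows beyond ±3 SD removed — a single pass, no iteration,
which is the simplest reading of the rule and is reproducible.

**log10 transform.** Zero counts (possible for basophils in coarse
analyzers) are shifted by half the smallest positive value in that column
before log10; positive values are transformed as-is, so `log10(0.1)` is
exactly −1.

**Survey variance.** No survey-design package is required: the weighted
least squares fit takes stratified-PSU Taylor-linearization variance, with
PSU-aggregated score contributions, the $n_h/(n_h-1)$ small-sample factor,
and no finite-population correction — the standard design-based default for
NHANES-like analyses. Single-PSU strata contribute no variance (with a
warning). In the degenerate design (equal weights, one PSU per row, one
stratum) the point estimate equals OLS and the variance equals the HC0
sandwich scaled by $n/(n-1)$, which the tests verify against the `sandwich`
package.

**Confidence intervals and p-values.** CIs are $\hat\beta \pm 1.96\,se$
with the multiplier fixed at 1.96 (not the exact normal quantile, and not a
t quantile) so that CI-to-SE reconstruction, `(upper − lower)/3.92`,
round-trips exactly; p-values use the matching normal reference. At the
cohort sizes involved ($n \gtrsim 10^3$) the normal/t distinction is below
rounding. The interaction-test calibration study in the test suite confirms
the nominal level holds at $n = 250$.

**Restricted cubic splines.** Harrell's truncated-power restricted basis,
default 4 knots at the 5th/35th/65th/95th exposure percentiles (3- and
5-knot defaults follow the same convention). Nonlinearity is a joint Wald
chi-square test of the nonlinear basis terms.

**LASSO with unpenalized covariates.** The objective is
$(1/2n)\|y - Z\gamma - X\beta\|^2 + \lambda\|\beta\|_1$ with covariates
$Z$ unpenalized. The implementation residualizes $y$ and $X$ on $Z$
(Frisch–Waugh, exact at the optimum) and runs cyclic coordinate descent
with warm starts down a decreasing penalty grid: 100 log-spaced values from
the stationarity bound $\lambda_{\max} = \max_j |x_j'r|/n$ down to
$10^{-4}\lambda_{\max}$. Penalized predictors are standardized to unit
variance before penalization — the subtypes span two orders of magnitude in
count scale, and an unstandardized penalty would be unit-dependent —
and coefficients are reported back on the original scale. Convergence is
checked against the KKT conditions (tolerance $10^{-10}$ on coefficient
changes). $\lambda^*$ is the 10-fold cross-validated minimum-MSE penalty
(the stated rule; *not* the 1-SE rule); the full pipeline, including
residualization, is refit inside each training fold. Ties in CV MSE break
toward the larger penalty. Folds are assigned in a canonical ordering of
the rows so the subject-to-fold map is row-order invariant given the seed.
Post-selection inference is deliberately naive: the selected subtypes are
refit jointly by OLS and reported without selection-adjusted corrections,
mirroring common practice in this literature.

**Meta-analysis.** Fixed-effect inverse-variance pooling when the Cochran
heterogeneity p is ≥ .05, DerSimonian–Laird random effects otherwise, with
$\tau^2$ truncated at zero. The .05 switch is hard-coded as the default but
exposed (`het_threshold`) because it is a convention, not a law. A single
study passes through unchanged with heterogeneity p reported as 1.

**MR.** The instrument-strength statistic is $F = (\beta_X/se_X)^2$, the
standard summary-data approximation; $F < 10$ marks a weak instrument. The
confounder screen removes SNPs with any confounder association below
$\alpha/(\#\text{SNPs} \times \#\text{confounders})$ — Bonferroni over all
tests performed. Palindromic (A/T, C/G) SNPs with effect-allele frequency
in (0.42, 0.58) are ambiguous and removed. IVW and Egger default to
fixed-effect (unscaled) variance with a multiplicative random-error variant
behind `variance = "multiplicative"`; under the generator's exact Gaussian
errors the fixed-effect intercept test is exactly calibrated, which the
1000-replicate type-I study verifies. Egger re-orients all SNPs to
positive exposure effect before fitting, a requirement for intercept
identifiability.

**MR-PRESSO.** The observed statistic is the weighted RSS around
leave-one-out IVW slopes; the null distribution is parametric-bootstrap:
$\beta_X^* \sim N(\beta_X, se_X)$,
$\beta_Y^* \sim N(b_{(-j)}\beta_{Xj}, se_Y)$, with the RSS recomputed per
simulation (vectorized over simulations; leave-one-out slopes are O(n) via
running totals). Tail p-values carry a $+1/(N+1)$ continuity correction, so
1000 simulations (the default) bound the smallest per-SNP p at
$\approx 10^{-3}$ — enough for a Bonferroni-adjusted call at .05 with up to
~50 instruments. The distortion test bootstraps the expected estimate shift
from removing random non-outlier subsets of the same size as the outlier
set.

# Pipeline

`run_pipeline()` chains the stages — exclusion → transform → single-marker
→ LASSO → multiple-marker → meta, and filter → IVW/Egger/PRESSO (with
outlier-corrected refits when PRESSO flags SNPs) — from one YAML config,
writes every stage as TSV plus a YAML run log (package version, seed,
parameters), and is byte-for-byte reproducible from (inputs, config,
seed). The package deliberately ships no shell executable: the functions
and this vignette are the interface, and the config file plus
`run_pipeline()` cover scripted use.

# Problem sizes used in the test suite

The calibration and recovery studies are sized to be decisive yet quick:
IVW coverage and Egger-intercept recovery use 500 replicates of 30-SNP
datasets; intercept and interaction type-I calibration use 1000 replicates
(exact binomial 95% acceptance bands); MR-PRESSO null behaviour and
planted-outlier detection use 200 replicates at 1000 simulations each; the
confounded-lymphocyte pattern uses 25 replicates of n = 10,000 cohorts.
These sizes give Monte-Carlo standard errors severalfold smaller than the
margins being tested.

# Known limitations

* Individual-level estimates are complete-case per model; no imputation.
* The survey machinery covers stratified two-stage designs with
  within-stratum PSU contrasts; replicate-weight designs are out of scope.
* MR assumes instruments are pre-pruned for LD; no clumping is performed.
* Weighted-median/mode MR estimators and multivariable MR are not
  implemented.
* The fixed/random meta switch makes the pooled estimator discontinuous in
  the data at the .05 boundary; this mirrors the analysis convention being
  reproduced rather than a statistical recommendation.
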