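Package: wbclung
Title: White Blood Cell Differentials and Lung Function: Association and
    Mendelian Randomization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for studying circulating white blood cell
    (WBC) differential counts and prebronchodilator lung function (FVC,
    FEV1). Implements covariate-adjusted single-marker linear models with
    optional complex-survey (stratified PSU, weighted, Taylor-linearized)
    variance, total-WBC outlier exclusion, log10 transforms for
    right-skewed subtypes, restricted cubic spline dose-response curves,
    effect-modification tests, LASSO selection of WBC subtypes with
    unpenalized covariates, mutually adjusted multiple-marker models, and
    fixed/random-effect inverse-variance meta-analysis with Cochran's Q.
    A second arm performs two-sample Mendelian randomization from GWAS
    summary statistics: allele harmonization, instrument-strength and
    confounder filtering, inverse-variance-weighted and MR-Egger
    estimation, and the MR-PRESSO resampling test for horizontal
    pleiotropy. A synthetic-data module generates cohorts and two-sample
    summary statistics with known ground truth so the whole pipeline runs
    and is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    glmnet,
    metafor,
    sandwich,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
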