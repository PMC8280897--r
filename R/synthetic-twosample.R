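#' Specify synthetic two-sample GWAS summary statistics
#'
#' Parameters for [generate_two_sample()], which emulates the summary-data
#' input of a two-sample Mendelian randomization analysis: per-SNP exposure
#' effects (e.g. on a WBC count, 10^9 cells/L per allele) from an exposure
#' GWAS and outcome effects (mL of lung function per allele) from an
#' outcome GWAS, with a configurable true causal effect, a direct
#' (pleiotropic) effect distribution, and optionally planted high-pleiotropy
#' outlier instruments.
#'
#' @param n_snps Number of independent instruments.
#' @param beta_x_range Range of absolute per-allele exposure effects; each
#'   SNP's true effect is uniform in this range with a random sign.
#' @param se_x,se_y Standard errors of the reported exposure and outcome
#'   effects (scalar or per-SNP vector).
#' @param causal_effect True effect of the exposure on the outcome, mL per
#'   10^9 cells/L.
#' @param pleiotropy_mean,pleiotropy_sd Mean and SD of the per-SNP direct
#'   effect on the outcome (mL per allele); `mean != 0` gives directional
#'   pleiotropy, `sd > 0` with `mean = 0` balanced pleiotropy.
#' @param n_outliers Number of planted outlier SNPs.
#' @param outlier_magnitude Direct effect added to each planted outlier
#'   (mL per allele).
#' @param eaf_range Effect-allele frequency bounds, inside (0, 1).
#' @param palindromic_fraction Proportion of A/T or C/G variants.
#' @param n_exposure,n_outcome GWAS sample sizes recorded in the output.
#' @param seed Integer seed.
#' @return An object of class `two_sample_spec`.
#' @export
two_sample_spec <- function(n_snps = 30L,
                            beta_x_range = c(0.05, 0.15),
                            se_x = 0.002,
                            se_y = 2,
                            causal_effect = 0,
                            pleiotropy_mean = 0,
                            pleiotropy_sd = 0,
                            n_outliers = 0L,
                            outlier_magnitude = 0,
                            eaf_range = c(0.1, 0.9),
                            palindromic_fraction = 0.1,
                            n_exposure = 62076L,
                            n_outcome = 4012L,
                            seed = 1L) {
  stopifnot(n_snps >= 1, n_outliers <= n_snps, n_outliers >= 0,
            all(se_x > 0), all(se_y > 0),
            length(eaf_range) == 2, eaf_range[1] > 0, eaf_range[2] < 1,
            eaf_range[1] < eaf_range[2])
  check_probability(palindromic_fraction, "palindromic_fraction")
  structure(list(
    n_snps = as.integer(n_snps), beta_x_range = beta_x_range,
    se_x = se_x, se_y = se_y, causal_effect = causal_effect,
    pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
    n_outliers = as.integer(n_outliers), outlier_magnitude = outlier_magnitude,
    eaf_range = eaf_range, palindromic_fraction = palindromic_fraction,
    n_exposure = as.integer(n_exposure), n_outcome = as.integer(n_outcome),
    seed = as.integer(seed)
  ), class = "two_sample_spec")
}

#' Generate harmonized two-sample summary statistics with known truth
#'
#' Per SNP j the outcome effect is
#' `beta_y[j] = causal_effect * beta_x_true[j] + alpha[j] + e`, with
#' `alpha[j]` drawn from the configured pleiotropy distribution (inflated by
#' `outlier_magnitude` for planted outliers) and oriented to the
#' exposure-increasing allele, and `e ~ N(0, se_y[j])`. The
#' reported exposure effect is `beta_x_true[j] + N(0, se_x[j])`. Alleles,
#' positions and effect-allele frequencies are generated so the table is a
#' valid harmonized instrument set.
#'
#' @param spec A `two_sample_spec`.
#' @return A list of class `two_sample_data` with components
#'   `instruments` (data.frame with columns `snp, chr, pos, effect_allele,
#'   other_allele, eaf, beta_exposure, se_exposure, p_exposure, n_exposure,
#'   beta_outcome, se_outcome, p_outcome, n_outcome`) and `truth` (list with
#'   `causal_effect`, `outlier_idx`, `alpha`, `beta_x_true`).
#' @export
generate_two_sample <- function(spec) {
  stopifnot(inherits(spec, "two_sample_spec"))
  n <- spec$n_snps
  if (n < 3) {
    warning("fewer than 3 instruments: MR-Egger will not be estimable downstream")
  }
  se_x <- rep_len(spec$se_x, n)
  se_y <- rep_len(spec$se_y, n)

  set.seed(substream_seed(spec$seed, "snps"))
  snp <- sprintf("rs%07d", sample.int(9999999, n))
  chr <- sample.int(22, n, replace = TRUE)
  pos <- sample.int(2e8, n, replace = TRUE)
  eaf <- stats::runif(n, spec$eaf_range[1], spec$eaf_range[2])
  pal <- stats::runif(n) < spec$palindromic_fraction
  pal_pairs <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  nonpal_pairs <- rbind(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"),
                        c("A", "C"), c("C", "A"), c("G", "T"), c("T", "G"))
  pick <- function(pairs, m) pairs[sample.int(nrow(pairs), m, replace = TRUE), , drop = FALSE]
  alleles <- matrix("", n, 2)
  if (any(pal)) alleles[pal, ] <- pick(pal_pairs, sum(pal))
  if (any(!pal)) alleles[!pal, ] <- pick(nonpal_pairs, sum(!pal))

  set.seed(substream_seed(spec$seed, "exposure"))
  beta_x_true <- stats::runif(n, spec$beta_x_range[1], spec$beta_x_range[2]) *
    sample(c(-1, 1), n, replace = TRUE)
  beta_x <- beta_x_true + stats::rnorm(n, 0, se_x)

  set.seed(substream_seed(spec$seed, "pleiotropy"))
  alpha <- stats::rnorm(n, spec$pleiotropy_mean, spec$pleiotropy_sd)
  outlier_idx <- integer(0)
  if (spec$n_outliers > 0) {
    outlier_idx <- sort(sample.int(n, spec$n_outliers))
    alpha[outlier_idx] <- alpha[outlier_idx] + spec$outlier_magnitude
  }

  # direct effects are defined on the exposure-increasing allele; re-orient
  # them to each SNP's reported allele so directional pleiotropy survives
  # the mixed allele coding of a harmonized table
  set.seed(substream_seed(spec$seed, "outcome"))
  beta_y <- spec$causal_effect * beta_x_true + sign(beta_x_true) * alpha +
    stats::rnorm(n, 0, se_y)

  instruments <- data.frame(
    snp = snp, chr = chr, pos = pos,
    effect_allele = alleles[, 1], other_allele = alleles[, 2],
    eaf = eaf,
    beta_exposure = beta_x, se_exposure = se_x,
    p_exposure = z_p(beta_x, se_x), n_exposure = spec$n_exposure,
    beta_outcome = beta_y, se_outcome = se_y,
    p_outcome = z_p(beta_y, se_y), n_outcome = spec$n_outcome,
    stringsAsFactors = FALSE
  )
  structure(list(
    instruments = instruments,
    truth = list(causal_effect = spec$causal_effect,
                 outlier_idx = outlier_idx,
                 alpha = alpha,
                 beta_x_true = beta_x_true),
    spec = spec
  ), class = "two_sample_data")
}
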