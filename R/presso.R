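# Leave-one-out IVW slopes for every SNP at once: O(n) given the totals.
loo_ivw_slopes <- function(bx, by, w) {
  Sxy <- sum(w * bx * by)
  Sxx <- sum(w * bx^2)
  (Sxy - w * bx * by) / (Sxx - w * bx^2)
}

#' MR-PRESSO: pleiotropy residual sum of squares and outlier test
#'
#' Detects horizontal pleiotropy by comparing the observed weighted residual
#' sum of squares around leave-one-out IVW fits with its parametric null
#' distribution. For each SNP j the leave-one-out IVW slope `b_(-j)` is
#' computed; the observed RSS is
#' `sum_j (beta_y_j - b_(-j) * beta_x_j)^2 / se_y_j^2`. The null
#' distribution is built by simulating
#' `beta_x* ~ N(beta_x, se_x)` and `beta_y* ~ N(b_(-j) * beta_x_j, se_y)`
#' and recomputing the RSS; the global p is the tail fraction with a
#' `+1/(N+1)` continuity correction. Per-SNP outlier p-values come from the
#' tail of each SNP's simulated weighted residual distribution,
#' Bonferroni-adjusted over instruments; SNPs with adjusted p below
#' `significance` are flagged outliers. When outliers exist, the distortion
#' test compares the outlier-removal shift of the IVW estimate with a
#' bootstrap distribution obtained by removing random non-outlier subsets
#' of the same size.
#'
#' @param instruments Harmonized instrument data.frame (canonical columns,
#'   `se_exposure` required for the simulation).
#' @param n_simulations Number of null simulations (>= 100; default 1000).
#' @param seed Integer seed for the resampling.
#' @param significance Level for the Bonferroni-adjusted outlier call.
#' @return A list of class `presso_result`: `rss_observed`, `global_p`,
#'   `outlier_p` (Bonferroni-adjusted, named by SNP), `outliers` (SNP ids),
#'   `distortion_p` (NA when no outliers), `ivw_all`, `ivw_outlier_corrected`
#'   (NULL when no outliers or too few SNPs remain), `n_simulations`,
#'   `seed`.
#' @export
mr_presso <- function(instruments, n_simulations = 1000, seed = 1L,
                      significance = 0.05) {
  n <- nrow(instruments)
  if (n < 4) stop("MR-PRESSO needs at least 4 instruments")
  if (n_simulations < 100) stop("n_simulations must be at least 100")
  bx <- instruments$beta_exposure
  by <- instruments$beta_outcome
  sx <- instruments$se_exposure
  sy <- instruments$se_outcome
  if (stats::sd(bx) == 0 && stats::sd(by) == 0) {
    stop("degenerate instruments: all (beta_exposure, beta_outcome) identical")
  }
  if (any(sx <= 0) || any(sy <= 0)) stop("standard errors must be positive")
  w <- 1 / sy^2

  b_loo <- loo_ivw_slopes(bx, by, w)
  resid_obs <- w * (by - b_loo * bx)^2
  rss_obs <- sum(resid_obs)

  set.seed(substream_seed(seed, "presso"))
  N <- as.integer(n_simulations)
  BX <- matrix(stats::rnorm(n * N, bx, sx), n, N)
  BY <- matrix(stats::rnorm(n * N, b_loo * bx, sy), n, N)
  Sxy <- colSums(w * BX * BY)
  Sxx <- colSums(w * BX^2)
  num <- sweep(w * BX * BY, 2, Sxy, function(a, b) b - a)   # Sxy - w bx by
  den <- sweep(w * BX^2, 2, Sxx, function(a, b) b - a)      # Sxx - w bx^2
  Bloo <- num / den
  RES <- w * (BY - Bloo * BX)^2
  rss_sim <- colSums(RES)

  global_p <- (1 + sum(rss_sim >= rss_obs)) / (N + 1)
  tail_counts <- rowSums(RES >= resid_obs)
  outlier_p_raw <- (1 + tail_counts) / (N + 1)
  outlier_p <- pmin(1, outlier_p_raw * n)
  names(outlier_p) <- instruments$snp
  outliers <- instruments$snp[outlier_p < significance]

  ivw_all <- mr_ivw(instruments)
  ivw_corrected <- NULL
  distortion_p <- NA_real_
  if (length(outliers) > 0 && n - length(outliers) >= 1) {
    keep <- !instruments$snp %in% outliers
    ivw_corrected <- mr_ivw(instruments[keep, , drop = FALSE])
    d_obs <- (ivw_all$estimate - ivw_corrected$estimate) /
      abs(ivw_corrected$estimate)
    n_out <- length(outliers)
    idx_keep <- which(keep)
    d_boot <- vapply(seq_len(N), function(i) {
      drop_idx <- sample(idx_keep, n_out)
      sub <- instruments[-drop_idx, , drop = FALSE]
      b <- mr_ivw(sub)$estimate
      (ivw_all$estimate - b) / abs(b)
    }, numeric(1))
    distortion_p <- (1 + sum(abs(d_boot) >= abs(d_obs))) / (N + 1)
  }
  structure(list(rss_observed = rss_obs, global_p = global_p,
                 outlier_p = outlier_p, outliers = outliers,
                 distortion_p = distortion_p,
                 ivw_all = ivw_all, ivw_outlier_corrected = ivw_corrected,
                 n_simulations = N, seed = seed),
            class = "presso_result")
}
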