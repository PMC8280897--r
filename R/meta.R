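#' Reconstruct a standard error from a 95% confidence interval
#'
#' `se = (ci_high - ci_low) / (2 * 1.96)`. The 1.96 multiplier is fixed (not
#' the exact normal quantile) to match the convention used when printing
#' normal CIs to two decimals; the difference is below rounding error.
#'
#' @param ci_low,ci_high CI bounds (vectorized).
#' @return Standard error(s).
#' @export
se_from_ci <- function(ci_low, ci_high) {
  if (any(!is.finite(ci_low)) || any(!is.finite(ci_high))) {
    stop("CI bounds must be finite")
  }
  if (any(ci_high <= ci_low)) stop("ci_high must exceed ci_low")
  (ci_high - ci_low) / (2 * Z95)
}

#' Cochran's Q heterogeneity test
#'
#' Fixed-effect inverse-variance pooled mean with weights `1/se^2`,
#' `Q = sum w_i (beta_i - pooled)^2`, and the chi-square p-value on `k - 1`
#' degrees of freedom. With a single study Q is undefined and the
#' heterogeneity p is reported as 1.
#'
#' @param betas,ses Per-study estimates and standard errors.
#' @return A list: `q_stat`, `het_p`, `pooled_fixed`, `k`.
#' @export
cochran_q <- function(betas, ses) {
  stopifnot(length(betas) == length(ses))
  if (any(ses <= 0)) stop("standard errors must be positive")
  k <- length(betas)
  w <- 1 / ses^2
  pooled <- sum(w * betas) / sum(w)
  if (k == 1) {
    return(list(q_stat = NA_real_, het_p = 1, pooled_fixed = pooled, k = k))
  }
  q <- sum(w * (betas - pooled)^2)
  list(q_stat = q,
       het_p = stats::pchisq(q, df = k - 1, lower.tail = FALSE),
       pooled_fixed = pooled, k = k)
}

#' Inverse-variance meta-analysis with a heterogeneity-driven model switch
#'
#' Pools per-cohort estimates by fixed-effect inverse-variance weighting
#' when the Cochran heterogeneity p is at or above the threshold (default
#' .05), and by DerSimonian-Laird random effects otherwise:
#' `tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))` with random
#' weights `1/(se^2 + tau2)`. A single study is passed through unchanged
#' (method `"fixed"`, heterogeneity p 1). The CI is
#' `pooled +/- 1.96 * pooled_se`.
#'
#' @inheritParams cochran_q
#' @param het_threshold Heterogeneity p below which random effects are used.
#' @return A one-row data.frame of class `meta_result`: `pooled_beta`,
#'   `pooled_se`, `ci_low`, `ci_high`, `p`, `q_stat`, `het_p`, `tau2`,
#'   `method`, `k`.
#' @export
pool_estimates <- function(betas, ses, het_threshold = 0.05) {
  cq <- cochran_q(betas, ses)
  w <- 1 / ses^2
  if (cq$k == 1 || cq$het_p >= het_threshold) {
    method <- "fixed"
    tau2 <- 0
    pw <- w
  } else {
    method <- "random"
    tau2 <- max(0, (cq$q_stat - (cq$k - 1)) / (sum(w) - sum(w^2) / sum(w)))
    pw <- 1 / (ses^2 + tau2)
  }
  pooled <- sum(pw * betas) / sum(pw)
  pooled_se <- sqrt(1 / sum(pw))
  out <- data.frame(pooled_beta = pooled, pooled_se = pooled_se,
                    ci_low = pooled - Z95 * pooled_se,
                    ci_high = pooled + Z95 * pooled_se,
                    p = z_p(pooled, pooled_se),
                    q_stat = cq$q_stat, het_p = cq$het_p, tau2 = tau2,
                    method = method, k = cq$k,
                    stringsAsFactors = FALSE)
  class(out) <- c("meta_result", "data.frame")
  out
}

#' Pool estimates given as (beta, 95% CI) triples
#'
#' Convenience wrapper for pooling rows printed as `beta (ci_low, ci_high)`
#' in a results table: SEs are reconstructed with [se_from_ci()] and passed
#' to [pool_estimates()].
#'
#' @param betas Point estimates.
#' @param ci_low,ci_high 95% CI bounds.
#' @inheritParams pool_estimates
#' @return See [pool_estimates()].
#' @export
pool_from_ci <- function(betas, ci_low, ci_high, het_threshold = 0.05) {
  pool_estimates(betas, se_from_ci(ci_low, ci_high),
                 het_threshold = het_threshold)
}
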