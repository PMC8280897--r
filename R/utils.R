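# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a reproducible substream seed from one global seed so that adding a
# new random field to the generator does not shift the draws of other fields.
# Result is kept inside 32-bit integer range.
substream_seed <- function(seed, stream) {
  offsets <- c(covariates = 11L, counts = 23L, noise = 37L, survey = 53L,
               snps = 67L, exposure = 79L, pleiotropy = 97L, outcome = 113L,
               folds = 131L, presso = 151L)
  if (!stream %in% names(offsets)) stop("unknown random stream: ", stream)
  as.integer((as.numeric(seed) * 7919 + offsets[[stream]]) %% 2147483629)
}

# Multivariate normal draws via the Cholesky factor; Sigma must be PSD.
rmvnorm_chol <- function(n, mu, Sigma) {
  k <- length(mu)
  L <- chol(Sigma + diag(1e-12, k))
  Z <- matrix(stats::rnorm(n * k), n, k)
  sweep(Z %*% L, 2, mu, `+`)
}

check_psd_correlation <- function(R, what = "correlation matrix") {
  if (!is.matrix(R) || nrow(R) != ncol(R)) {
    stop(what, " must be a square matrix")
  }
  if (max(abs(R - t(R))) > 1e-8) stop(what, " must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-8) stop(what, " must have unit diagonal")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop(what, " is not positive semi-definite (smallest eigenvalue ",
         format(min(ev), digits = 4), ")")
  }
  invisible(R)
}

check_probability <- function(p, name) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop(name, " must lie in [0, 1]")
  }
  invisible(p)
}

# Normal-reference two-sided p-value; the package reports normal CIs with a
# fixed 1.96 multiplier throughout, so p-values use the matching reference.
z_p <- function(est, se) 2 * stats::pnorm(-abs(est / se))

Z95 <- 1.96
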