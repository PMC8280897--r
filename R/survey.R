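# Design-based variance for weighted least squares under a stratified
# multi-stage design, by Taylor linearization: score contributions
# u_i = w_i * x_i * e_i are summed within PSU, and their between-PSU
# within-stratum covariance (with the n_h/(n_h - 1) small-sample factor and
# no finite-population correction) is sandwiched between (X'WX)^-1.
# Strata with a single PSU cannot contribute a between-PSU contrast and are
# dropped from the variance with a warning (certainty-PSU convention).
svy_taylor_vcov <- function(X, resid, weights, stratum, psu) {
  U <- X * (weights * resid)
  XtWX <- crossprod(X, X * weights)
  XtWXinv <- solve(XtWX)
  G <- matrix(0, ncol(X), ncol(X))
  lonely <- character(0)
  for (h in unique(stratum)) {
    rows <- which(stratum == h)
    groups <- split(rows, psu[rows])
    n_h <- length(groups)
    if (n_h < 2) {
      lonely <- c(lonely, as.character(h))
      next
    }
    Zh <- t(vapply(groups, function(idx) colSums(U[idx, , drop = FALSE]),
                   numeric(ncol(X))))
    Zc <- sweep(Zh, 2, colMeans(Zh))
    G <- G + (n_h / (n_h - 1)) * crossprod(Zc)
  }
  if (length(lonely) > 0) {
    warning("strata with a single PSU contribute no variance: ",
            paste(lonely, collapse = ", "))
  }
  XtWXinv %*% G %*% XtWXinv
}
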