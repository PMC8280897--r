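#' Restricted cubic spline basis
#'
#' Truncated-power restricted (natural) cubic spline basis in Harrell's
#' parameterization: for knots `t_1 < ... < t_k` the basis has the linear
#' term plus `k - 2` nonlinear terms
#' \deqn{[(x-t_j)_+^3 - (x-t_{k-1})_+^3 (t_k-t_j)/(t_k-t_{k-1})
#'       + (x-t_k)_+^3 (t_{k-1}-t_j)/(t_k-t_{k-1})] / (t_k-t_1)^2,}
#' which is linear beyond the boundary knots.
#'
#' @param x Numeric vector.
#' @param knots Increasing numeric vector of knot locations (length >= 3).
#' @return A matrix with `length(knots) - 1` columns; the first is `x`.
#' @export
rcs_basis <- function(x, knots) {
  k <- length(knots)
  if (k < 3) stop("at least 3 knots are required")
  if (is.unsorted(knots, strictly = TRUE)) stop("knots must be strictly increasing")
  pos3 <- function(u) pmax(u, 0)^3
  tk <- knots[k]; tk1 <- knots[k - 1]; t1 <- knots[1]
  B <- matrix(0, length(x), k - 1)
  B[, 1] <- x
  for (j in seq_len(k - 2)) {
    B[, j + 1] <- (pos3(x - knots[j]) -
                     pos3(x - tk1) * (tk - knots[j]) / (tk - tk1) +
                     pos3(x - tk) * (tk1 - knots[j]) / (tk - tk1)) / (tk - t1)^2
  }
  colnames(B) <- c("lin", paste0("nl", seq_len(k - 2)))
  B
}

default_knot_quantiles <- function(n_knots) {
  switch(as.character(n_knots),
         "3" = c(0.10, 0.50, 0.90),
         "4" = c(0.05, 0.35, 0.65, 0.95),
         "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
         seq(0.05, 0.95, length.out = n_knots))
}

#' Restricted cubic spline dose-response fit
#'
#' Explores the shape of the exposure/outcome relationship with a
#' restricted cubic spline for the exposure plus linear covariate
#' adjustment. Returns the covariate-adjusted exposure curve on a grid and
#' a joint Wald test of the nonlinear spline terms (nonlinearity p).
#'
#' @inheritParams fit_single_marker
#' @param n_knots Number of knots (>= 3; default 4, at the 5th/35th/65th/
#'   95th exposure percentiles).
#' @param knots Optional explicit knot locations (overrides `n_knots`).
#' @param grid_n Number of grid points for the fitted curve.
#' @return A list of class `rcs_fit`: `curve` (data.frame `x`, `yhat`; the
#'   exposure contribution centred at the exposure median), `p_nonlinear`,
#'   `wald_chisq`, `df`, `knots`, `coefficients`.
#' @export
fit_rcs <- function(table, exposure, outcome, covariates = character(),
                    n_knots = 4, knots = NULL, grid_n = 100) {
  if (is.null(knots)) {
    if (n_knots < 3) stop("n_knots must be at least 3")
    knots <- unique(stats::quantile(table[[exposure]],
                                    default_knot_quantiles(n_knots),
                                    na.rm = TRUE, names = FALSE))
  }
  if (length(knots) < 3) stop("fewer than 3 distinct knots in the exposure")
  d <- assoc_frame(table, c(outcome, exposure, covariates))
  if (length(unique(d[[exposure]])) < length(knots)) {
    stop("exposure has fewer distinct values than knots")
  }
  covariates <- prune_covariates(d, covariates)
  B <- rcs_basis(d[[exposure]], knots)
  Z <- if (length(covariates) > 0) {
    stats::model.matrix(stats::reformulate(covariates), d)
  } else {
    matrix(1, nrow(d), 1, dimnames = list(NULL, "(Intercept)"))
  }
  X <- cbind(Z, B)
  check_full_rank(X)
  fit <- stats::lm.fit(X, d[[outcome]])
  sigma2 <- sum(fit$residuals^2) / fit$df.residual
  V <- sigma2 * chol2inv(chol(crossprod(X)))
  nl <- grep("^nl", colnames(X))
  b_nl <- fit$coefficients[nl]
  W <- tryCatch(drop(t(b_nl) %*% solve(V[nl, nl, drop = FALSE], b_nl)),
                error = function(e) NA_real_)
  p_nl <- if (is.na(W)) NA_real_ else stats::pchisq(W, df = length(nl),
                                                    lower.tail = FALSE)
  grid <- seq(min(d[[exposure]]), max(d[[exposure]]), length.out = grid_n)
  Bg <- rcs_basis(grid, knots)
  spl_coef <- fit$coefficients[colnames(B)]
  yg <- drop(Bg %*% spl_coef)
  ref <- drop(rcs_basis(stats::median(d[[exposure]]), knots) %*% spl_coef)
  structure(list(curve = data.frame(x = grid, yhat = yg - ref),
                 p_nonlinear = p_nl, wald_chisq = W, df = length(nl),
                 knots = knots, coefficients = fit$coefficients),
            class = "rcs_fit")
}
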