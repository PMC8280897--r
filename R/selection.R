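#' LASSO configuration
#'
#' Settings for [select_lasso()]: the penalty grid, the cross-validation
#' layout and the fold-assignment seed.
#'
#' @param lambda_grid Optional decreasing vector of positive penalties; when
#'   `NULL` a grid of `n_lambda` log-spaced values from the data-derived
#'   `lambda_max` down to `lambda_max * lambda_min_ratio` is used.
#' @param n_lambda Grid size (default 100).
#' @param lambda_min_ratio Ratio of the smallest to the largest penalty.
#' @param n_folds Number of CV folds (default 10).
#' @param standardize Standardize penalized predictors to unit variance
#'   before penalization (coefficients are reported on the original scale).
#' @param seed Integer seed for the fold assignment.
#' @param tol,max_iter Coordinate-descent convergence tolerance (max
#'   absolute coefficient change) and iteration cap.
#' @return An object of class `lasso_config`.
#' @export
lasso_config <- function(lambda_grid = NULL, n_lambda = 100,
                         lambda_min_ratio = 1e-4, n_folds = 10,
                         standardize = TRUE, seed = 1L,
                         tol = 1e-10, max_iter = 100000L) {
  if (!is.null(lambda_grid)) {
    if (any(lambda_grid <= 0)) stop("lambda_grid must be strictly positive")
    if (is.unsorted(rev(lambda_grid), strictly = TRUE)) {
      stop("lambda_grid must be strictly decreasing")
    }
  }
  if (n_folds < 2) stop("n_folds must be >= 2")
  structure(list(lambda_grid = lambda_grid, n_lambda = n_lambda,
                 lambda_min_ratio = lambda_min_ratio,
                 n_folds = as.integer(n_folds),
                 standardize = isTRUE(standardize), seed = as.integer(seed),
                 tol = tol, max_iter = as.integer(max_iter)),
            class = "lasso_config")
}

# Cyclic coordinate descent for (1/(2n)) ||y - X b||^2 + lambda ||b||_1 on
# centred predictors with mean(x_j^2) precomputed. Returns exact zeros via
# soft thresholding; convergence is verified against the KKT conditions.
coord_descent <- function(X, y, lambda, b0 = NULL, tol = 1e-10,
                          max_iter = 100000L) {
  n <- nrow(X); p <- ncol(X)
  xsq <- colMeans(X^2)
  b <- b0 %||% numeric(p)
  r <- y - drop(X %*% b)
  soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_len(p)) {
      if (xsq[j] == 0) next
      zj <- sum(X[, j] * r) / n + xsq[j] * b[j]
      bj_new <- soft(zj, lambda) / xsq[j]
      if (bj_new != b[j]) {
        r <- r + X[, j] * (b[j] - bj_new)
        delta <- max(delta, abs(bj_new - b[j]))
        b[j] <- bj_new
      }
    }
    if (delta < tol) break
  }
  grad <- drop(crossprod(X, r)) / n
  kkt_ok <- all(abs(grad[b == 0]) <= lambda + 1e-6 * max(1, lambda)) &&
    (sum(b != 0) == 0 ||
       max(abs(grad[b != 0] - lambda * sign(b[b != 0]))) <= 1e-6 * max(1, lambda))
  if (it >= max_iter && !kkt_ok) {
    stop("coordinate descent did not converge at lambda = ", lambda,
         " after ", max_iter, " iterations (max KKT violation ",
         format(max(abs(grad)) - lambda, digits = 3), ")")
  }
  b
}

# Residualize y and the penalized block on the unpenalized columns
# (intercept always included) via QR -- the Frisch-Waugh step that keeps
# covariates unpenalized.
residualize <- function(y, Xp, Z) {
  q <- qr(Z)
  list(ry = qr.resid(q, y),
       RX = apply(Xp, 2, function(col) qr.resid(q, col)),
       qr = q)
}

lasso_path <- function(RX, ry, lambda_grid, standardize, tol, max_iter) {
  n <- nrow(RX)
  s <- if (standardize) sqrt(colMeans(RX^2)) else rep(1, ncol(RX))
  s[s == 0] <- 1
  Xs <- sweep(RX, 2, s, `/`)
  B <- matrix(0, ncol(RX), length(lambda_grid),
              dimnames = list(colnames(RX), NULL))
  b <- numeric(ncol(RX))
  for (i in seq_along(lambda_grid)) {
    b <- coord_descent(Xs, ry, lambda_grid[i], b0 = b, tol = tol,
                       max_iter = max_iter)
    B[, i] <- b / s
  }
  B
}

#' Smallest penalty that zeroes all penalized coefficients
#'
#' The stationarity bound `lambda_max = max_j |x_j' r| / n` computed on the
#' covariate-residualized (and, by default, standardized) penalized
#' predictors, where `r` is the covariate-residualized outcome.
#'
#' @inheritParams select_lasso
#' @return A single penalty value.
#' @export
lasso_lambda_max <- function(table, outcome, penalized,
                             unpenalized = character(),
                             standardize = TRUE) {
  d <- assoc_frame(table, c(outcome, penalized, unpenalized))
  Z <- stats::model.matrix(
    if (length(unpenalized) > 0) stats::reformulate(unpenalized) else ~1, d)
  Xp <- as.matrix(d[, penalized, drop = FALSE])
  rz <- residualize(d[[outcome]], Xp, Z)
  s <- if (standardize) sqrt(colMeans(rz$RX^2)) else rep(1, ncol(rz$RX))
  s[s == 0] <- 1
  max(abs(crossprod(sweep(rz$RX, 2, s, `/`), rz$ry))) / nrow(rz$RX)
}

#' LASSO selection of WBC subtypes with unpenalized covariates
#'
#' Selects, among candidate WBC exposures, those with nonzero coefficients
#' at the penalty minimizing the K-fold cross-validated mean squared error.
#' Covariates enter the model without penalization: the outcome and the
#' penalized block are residualized on the covariates (Frisch-Waugh), the
#' penalized problem is solved by cyclic coordinate descent over a
#' decreasing penalty grid with warm starts, and covariate coefficients are
#' recovered by back-substitution. Penalized predictors are standardized to
#' unit variance before penalization (by default) and reported on the
#' original scale. Ties in the CV curve are broken toward the larger
#' penalty (the sparser model).
#'
#' @param table Cohort data.frame.
#' @param outcome Outcome column (mL).
#' @param penalized Candidate exposure columns subject to the L1 penalty.
#'   Conventionally these are the subtypes whose single-marker p was below
#'   .05.
#' @param unpenalized Covariate columns entered without penalization.
#' @param config A [lasso_config()].
#' @return A list of class `lasso_selection`: `selected` (exposure names
#'   with nonzero coefficient at `lambda_min`), `lambda_min`, `lambda_grid`,
#'   `cv_mse` (mean CV MSE per penalty), `coefficients` (penalized, original
#'   scale, at `lambda_min`), `covariate_coefficients`, `n_used`.
#' @export
select_lasso <- function(table, outcome, penalized,
                         unpenalized = character(),
                         config = lasso_config()) {
  stopifnot(inherits(config, "lasso_config"))
  if (length(penalized) == 0) {
    message("empty candidate set: nothing to select")
    return(structure(list(selected = character(0), lambda_min = NA_real_,
                          lambda_grid = numeric(0), cv_mse = numeric(0),
                          coefficients = numeric(0),
                          covariate_coefficients = numeric(0), n_used = 0L),
                     class = "lasso_selection"))
  }
  d <- assoc_frame(table, c(outcome, penalized, unpenalized))
  n <- nrow(d)
  Zform <- if (length(unpenalized) > 0) stats::reformulate(unpenalized) else ~1
  Z <- stats::model.matrix(Zform, d)
  Xp <- as.matrix(d[, penalized, drop = FALSE])
  y <- d[[outcome]]

  rz <- residualize(y, Xp, Z)
  lambda_grid <- config$lambda_grid
  if (is.null(lambda_grid)) {
    s <- if (config$standardize) sqrt(colMeans(rz$RX^2)) else rep(1, ncol(rz$RX))
    s[s == 0] <- 1
    lmax <- max(abs(crossprod(sweep(rz$RX, 2, s, `/`), rz$ry))) / n
    lambda_grid <- exp(seq(log(lmax), log(lmax * config$lambda_min_ratio),
                           length.out = config$n_lambda))
  }

  # cross-validation: refit the whole pipeline (residualization included)
  # inside each training fold, predict the raw outcome on the held-out fold.
  # Folds are assigned in a canonical ordering of the rows (by outcome, then
  # predictors) so that, given the seed, the subject-to-fold map does not
  # depend on row order.
  set.seed(substream_seed(config$seed, "folds"))
  canon <- do.call(order, c(list(y), as.data.frame(Xp)))
  folds <- integer(n)
  folds[canon] <- sample(rep_len(seq_len(config$n_folds), n))
  sqerr <- matrix(NA_real_, n, length(lambda_grid))
  for (k in seq_len(config$n_folds)) {
    tr <- folds != k
    Ztr <- Z[tr, , drop = FALSE]
    rz_tr <- residualize(y[tr], Xp[tr, , drop = FALSE], Ztr)
    Btr <- lasso_path(rz_tr$RX, rz_tr$ry, lambda_grid, config$standardize,
                      config$tol, config$max_iter)
    # covariate coefficients at each lambda: gamma = (Z'Z)^-1 Z'(y - Xp b)
    resid_y <- y[tr] - Xp[tr, , drop = FALSE] %*% Btr       # n_tr x L
    Gam <- qr.coef(rz_tr$qr, resid_y)                        # q x L
    Gam[is.na(Gam)] <- 0
    pred <- Z[!tr, , drop = FALSE] %*% Gam +
      Xp[!tr, , drop = FALSE] %*% Btr
    sqerr[!tr, ] <- (y[!tr] - pred)^2
  }
  cv_mse <- colMeans(sqerr)
  i_min <- which(cv_mse == min(cv_mse))[1]   # grid is decreasing: first = sparser
  lambda_min <- lambda_grid[i_min]

  B <- lasso_path(rz$RX, rz$ry, lambda_grid, config$standardize,
                  config$tol, config$max_iter)
  b <- B[, i_min]
  gam <- qr.coef(rz$qr, y - drop(Xp %*% b))
  gam[is.na(gam)] <- 0
  structure(list(selected = penalized[b != 0], lambda_min = lambda_min,
                 lambda_grid = lambda_grid, cv_mse = cv_mse,
                 coefficients = stats::setNames(b, penalized),
                 covariate_coefficients = gam, n_used = n,
                 path = B),
            class = "lasso_selection")
}

#' Mutually adjusted multiple-marker model
#'
#' Fits one OLS model containing all selected WBC exposures jointly plus
#' the covariates, and reports a covariate-adjusted, mutually adjusted
#' estimate per exposure (model tag `"multiple"`).
#'
#' @inheritParams fit_single_marker
#' @param exposures Character vector of selected exposure columns.
#' @param cor_threshold Absolute pairwise correlation among exposures above
#'   which the fit is refused (near-collinear markers).
#' @return A data.frame of `AssociationEstimate` rows, one per exposure.
#' @export
fit_multiple_marker <- function(table, exposures, outcome,
                                covariates = character(),
                                cor_threshold = 0.999) {
  if (length(exposures) < 1) stop("at least one selected exposure is required")
  d <- assoc_frame(table, c(outcome, exposures, covariates))
  covariates <- prune_covariates(d, covariates)
  if (length(exposures) > 1) {
    C <- abs(stats::cor(d[, exposures, drop = FALSE]))
    diag(C) <- 0
    if (max(C) > cor_threshold) {
      ij <- which(C == max(C), arr.ind = TRUE)[1, ]
      stop("exposures '", exposures[ij[1]], "' and '", exposures[ij[2]],
           "' are collinear (|r| = ", format(max(C), digits = 4), ")")
    }
  }
  form <- stats::reformulate(c(exposures, covariates), response = outcome)
  X <- stats::model.matrix(form, d)
  check_full_rank(X)
  fit <- stats::lm.fit(X, d[[outcome]])
  sigma2 <- sum(fit$residuals^2) / fit$df.residual
  XtXinv <- chol2inv(chol(crossprod(X)))
  rows <- lapply(exposures, function(e) {
    j <- match(e, colnames(X))
    estimate_row(e, outcome, unname(fit$coefficients[e]),
                 sqrt(sigma2 * XtXinv[j, j]), nrow(d), "multiple")
  })
  do.call(rbind, rows)
}
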