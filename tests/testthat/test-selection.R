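make_lasso_fixture <- function(n = 200, seed = 5) {
  set.seed(seed)
  d <- data.frame(age = rnorm(n, 60, 8), sex = rbinom(n, 1, 0.5))
  d$neutrophils <- rlnorm(n, log(3.2), 0.3)
  d$lymphocytes <- rlnorm(n, log(1.6), 0.25)
  d$monocytes <- rlnorm(n, log(0.3), 0.3)
  d$fvc <- 3000 - 30 * d$neutrophils - 15 * d$lymphocytes -
    20 * d$age + 350 * d$sex + rnorm(n, 0, 150)
  d
}

test_that("the lambda -> 0 limit reproduces the joint OLS fit", {
  d <- make_lasso_fixture()
  pen <- c("neutrophils", "lymphocytes", "monocytes")
  lmax <- lasso_lambda_max(d, "fvc", pen, c("age", "sex"))
  sel <- select_lasso(d, "fvc", pen, c("age", "sex"),
                      lasso_config(lambda_grid = c(lmax, lmax / 10, 1e-8),
                                   n_folds = 3, seed = 1))
  ols <- lm(fvc ~ neutrophils + lymphocytes + monocytes + age + sex, data = d)
  expect_equal(unname(sel$path[, 3]), unname(coef(ols)[pen]), tolerance = 1e-6)
})

test_that("penalties at or above lambda_max zero out every penalized coefficient", {
  d <- make_lasso_fixture()
  pen <- c("neutrophils", "lymphocytes", "monocytes")
  lmax <- lasso_lambda_max(d, "fvc", pen, c("age", "sex"))
  sel <- select_lasso(d, "fvc", pen, c("age", "sex"),
                      lasso_config(lambda_grid = lmax * 1.0001,
                                   n_folds = 3, seed = 1))
  expect_true(all(sel$path[, 1] == 0))
  # just below lambda_max at least one coefficient activates
  sel2 <- select_lasso(d, "fvc", pen, c("age", "sex"),
                       lasso_config(lambda_grid = c(lmax, lmax * 0.95),
                                    n_folds = 3, seed = 1))
  expect_true(any(sel2$path[, 2] != 0))
})

test_that("the two-predictor solution beats a brute-force objective grid", {
  set.seed(8)
  n <- 120
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  d$y <- 1.5 * d$x1 - 0.8 * d$x2 + rnorm(n, 0, 1)
  lambda <- 0.3
  sel <- select_lasso(d, "y", c("x1", "x2"), character(),
                      lasso_config(lambda_grid = lambda, n_folds = 3, seed = 2))
  # objective on the centred, standardized data the solver sees
  ry <- d$y - mean(d$y)
  Xs <- scale(d[, c("x1", "x2")], center = TRUE, scale = FALSE)
  s <- sqrt(colMeans(Xs^2))
  Xs <- sweep(Xs, 2, s, `/`)
  obj <- function(b) sum((ry - Xs %*% b)^2) / (2 * n) + lambda * sum(abs(b))
  b_hat <- sel$coefficients * s       # back to the standardized scale
  grid <- as.matrix(expand.grid(b1 = seq(-2, 2, by = 0.01),
                                b2 = seq(-2, 2, by = 0.01)))
  grid_obj <- apply(grid, 1, obj)
  expect_lte(obj(b_hat), min(grid_obj) + 1e-10)
})

test_that("orthogonalized exposures give joint betas equal to single-marker betas", {
  set.seed(12)
  n <- 150
  x1 <- rnorm(n)
  x2 <- residuals(lm(rnorm(n) ~ x1))   # exactly orthogonal to x1
  x2 <- x2 - mean(x2)
  d <- data.frame(x1 = x1 - mean(x1), x2 = x2)
  d$y <- 5 + 2 * d$x1 - 3 * d$x2 + rnorm(n)
  joint <- fit_multiple_marker(d, c("x1", "x2"), "y")
  s1 <- fit_single_marker(d, "x1", "y")
  s2 <- fit_single_marker(d, "x2", "y")
  expect_equal(joint$beta[1], s1$beta, tolerance = 1e-8)
  expect_equal(joint$beta[2], s2$beta, tolerance = 1e-8)
})

test_that("a single selected exposure reduces to the single-marker model exactly", {
  d <- make_lasso_fixture()
  mm <- fit_multiple_marker(d, "neutrophils", "fvc", c("age", "sex"))
  sm <- fit_single_marker(d, "neutrophils", "fvc", c("age", "sex"))
  expect_equal(mm$beta, sm$beta)
  expect_equal(mm$se, sm$se)
  expect_identical(mm$model, "multiple")
})

test_that("collinear selected exposures are refused with the pair named", {
  d <- make_lasso_fixture()
  d$neutrophils_copy <- d$neutrophils
  expect_error(
    fit_multiple_marker(d, c("neutrophils", "neutrophils_copy"), "fvc", "age"),
    "neutrophils_copy")
})

test_that("the coordinate-descent path matches glmnet on a penalized-only problem", {
  skip_if_not_installed("glmnet")
  d <- make_lasso_fixture(n = 150, seed = 9)
  pen <- c("neutrophils", "lymphocytes", "monocytes")
  lmax <- lasso_lambda_max(d, "fvc", pen)
  lams <- c(lmax * 0.5, lmax * 0.1, lmax * 0.01)
  sel <- select_lasso(d, "fvc", pen, character(),
                      lasso_config(lambda_grid = lams, n_folds = 3, seed = 1))
  g <- glmnet::glmnet(as.matrix(d[, pen]), d$fvc, lambda = lams,
                      standardize = TRUE, thresh = 1e-14)
  expect_equal(unname(as.matrix(g$beta)), unname(sel$path), tolerance = 1e-4)
})

test_that("coefficient magnitudes are monotone along the path for orthonormal designs", {
  set.seed(3)
  n <- 64
  X <- qr.Q(qr(matrix(rnorm(n * 3), n, 3))) * sqrt(n)   # orthonormal columns
  d <- as.data.frame(X)
  names(d) <- c("a", "b", "c")
  d$y <- 2 * d$a - 1 * d$b + 0.5 * d$c + rnorm(n, 0, 0.5)
  lmax <- lasso_lambda_max(d, "y", c("a", "b", "c"))
  grid <- exp(seq(log(lmax), log(lmax * 1e-3), length.out = 30))
  sel <- select_lasso(d, "y", c("a", "b", "c"), character(),
                      lasso_config(lambda_grid = grid, n_folds = 2, seed = 1))
  for (j in 1:3) {
    expect_true(all(diff(abs(sel$path[j, ])) >= -1e-8))
  }
})

test_that("unpenalized covariates survive penalties that zero all exposures", {
  d <- make_lasso_fixture()
  pen <- c("neutrophils", "lymphocytes", "monocytes")
  lmax <- lasso_lambda_max(d, "fvc", pen, c("age", "sex"))
  sel <- select_lasso(d, "fvc", pen, c("age", "sex"),
                      lasso_config(lambda_grid = lmax * 2, n_folds = 3, seed = 1))
  expect_true(all(sel$coefficients == 0))
  expect_gt(abs(sel$covariate_coefficients["age"]), 1)
})

test_that("selection is seed-reproducible and invariant to row order", {
  d <- make_lasso_fixture(n = 250, seed = 17)
  pen <- c("neutrophils", "lymphocytes", "monocytes")
  cfg <- lasso_config(n_folds = 5, seed = 42)
  a <- select_lasso(d, "fvc", pen, c("age", "sex"), cfg)
  b <- select_lasso(d, "fvc", pen, c("age", "sex"), cfg)
  expect_identical(a$selected, b$selected)
  expect_identical(a$cv_mse, b$cv_mse)
  set.seed(99)
  perm <- sample(nrow(d))
  c_ <- select_lasso(d[perm, ], "fvc", pen, c("age", "sex"), cfg)
  expect_identical(a$selected, c_$selected)
  expect_equal(a$lambda_min, c_$lambda_min)
})

test_that("an empty candidate set returns an empty selection with a notice", {
  d <- make_lasso_fixture()
  expect_message(sel <- select_lasso(d, "fvc", character(), "age"),
                 "empty candidate")
  expect_length(sel$selected, 0)
})
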