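test_that("total-WBC outlier exclusion matches a direct z-score oracle", {
  set.seed(21)
  x <- c(rnorm(99, 6.0, 0.5), 8.0)
  tab <- data.frame(subject_id = sprintf("S%03d", 1:100), wbc_total = x)
  res <- exclude_wbc_outliers(tab)
  z <- abs(x - mean(x)) / sd(x)
  expect_setequal(res$excluded$subject_id, tab$subject_id[z > 3])
  expect_equal(nrow(res$table), sum(z <= 3))
  expect_equal(unname(res$bounds),
               c(mean(x) - 3 * sd(x), mean(x) + 3 * sd(x)))
})

test_that("degenerate and empty inputs pass through the outlier filter", {
  tab <- data.frame(subject_id = c("a", "b"), wbc_total = c(5, 5))
  expect_warning(res <- exclude_wbc_outliers(tab), "zero SD")
  expect_identical(res$table, tab)

  empty <- tab[0, ]
  res0 <- exclude_wbc_outliers(empty)
  expect_equal(nrow(res0$table), 0)
  expect_equal(nrow(res0$excluded), 0)
})

test_that("log10 transform follows the documented offset rule and touches nothing else", {
  tab <- data.frame(neutrophils = c(3.1, 2.9, 4.0),
                    eosinophils = c(0.1, 0.2, 0.05),
                    basophils = c(0, 0.04, 0.08))
  out <- transform_counts(tab)
  expect_equal(out$eosinophils_log10[1], -1)
  offset <- min(tab$basophils[tab$basophils > 0]) / 2
  expect_equal(out$basophils_log10[1], log10(offset))
  expect_equal(out$basophils_log10[2:3], log10(c(0.04, 0.08)))
  expect_identical(out$neutrophils, tab$neutrophils)

  neg <- data.frame(eosinophils = c(0.1, -0.2))
  expect_warning(out2 <- transform_counts(neg), "negative")
  expect_equal(nrow(out2), 1)
})

test_that("OLS path equals the normal-equations oracle to 1e-8", {
  d <- make_assoc_fixture(n = 20, seed = 42)
  est <- fit_single_marker(d, "neutrophils", "fvc",
                           c("age", "sex", "height", "smoking"))
  X <- cbind(1, as.matrix(d[, c("neutrophils", "age", "sex", "height", "smoking")]))
  colnames(X)[1] <- "(Intercept)"
  oracle <- ols_oracle(X, d$fvc)
  expect_equal(est$beta, unname(oracle$beta["neutrophils"]), tolerance = 1e-8)
  expect_equal(est$se, unname(oracle$se["neutrophils"]), tolerance = 1e-8)
  expect_equal(est$ci_low, est$beta - 1.96 * est$se)
  expect_equal(est$ci_high, est$beta + 1.96 * est$se)
})

test_that("a noiseless configured slope is recovered exactly", {
  sp <- small_cohort_spec(n = 120, noise = c(fvc = 0, fev1 = 0))
  d <- generate_cohort(sp)
  est <- fit_single_marker(d, "wbc_total", "fvc", c("age", "sex", "height"))
  expect_equal(est$beta, -30, tolerance = 1e-8)
  expect_lt(est$p, 1e-12)
})

test_that("degenerate survey design reduces to unweighted OLS; variance matches sandwich", {
  skip_if_not_installed("sandwich")
  d <- make_assoc_fixture(n = 40, seed = 7)
  d$survey_stratum <- 1L
  d$survey_psu <- seq_len(nrow(d))
  d$survey_weight <- 1
  des <- fit_single_marker(d, "neutrophils", "fvc", c("age", "sex"),
                           design = TRUE)
  ols <- fit_single_marker(d, "neutrophils", "fvc", c("age", "sex"))
  expect_equal(des$beta, ols$beta, tolerance = 1e-10)

  # in the single-stratum, one-row-per-PSU, equal-weight layout the Taylor
  # variance equals the HC0 sandwich scaled by n/(n - 1)
  fit <- lm(fvc ~ neutrophils + age + sex, data = d)
  V_hc <- sandwich::vcovHC(fit, type = "HC0") * nrow(d) / (nrow(d) - 1)
  expect_equal(des$se, sqrt(V_hc["neutrophils", "neutrophils"]),
               tolerance = 1e-8)
})

test_that("rank-deficient designs raise an error naming the collinear column", {
  d <- make_assoc_fixture(n = 25)
  d$age2 <- d$age
  expect_error(fit_single_marker(d, "neutrophils", "fvc", c("age", "age2")),
               "age2")
})

test_that("estimates are invariant to row and covariate order", {
  d <- make_assoc_fixture(n = 30, seed = 10)
  a <- fit_single_marker(d, "neutrophils", "fvc", c("age", "sex", "height"))
  b <- fit_single_marker(d[sample(nrow(d)), ], "neutrophils", "fvc",
                         c("height", "age", "sex"))
  expect_equal(a$beta, b$beta, tolerance = 1e-10)
  expect_equal(a$se, b$se, tolerance = 1e-10)
})

test_that("a planted sex-by-exposure interaction is detected and bracketed", {
  sp <- small_cohort_spec(
    n = 8000, seed = 31,
    noise = c(fvc = 250, fev1 = 250),
    effects = list(fvc = c(wbc_total = -10, age = -20, height = 20, sex = 300),
                   fev1 = c(wbc_total = -10, age = -20, height = 16, sex = 250)),
    interactions = list(list(outcome = "fvc", modifier = "sex",
                             exposure = "wbc_total", delta = -30)))
  d <- generate_cohort(sp)
  res <- fit_interaction(d, "wbc_total", "fvc", "sex", c("age", "height"))
  expect_lt(res$p_interaction, 0.001)
  b0 <- res$strata$beta[res$strata$level == 0]
  b1 <- res$strata$beta[res$strata$level == 1]
  expect_gt(b0, b1)           # female slope -10, male slope -40
  expect_lt(b1, -20)
  expect_gt(b0, -25)
})

test_that("constant modifiers are rejected and tiny strata are omitted with a warning", {
  d <- make_assoc_fixture(n = 30)
  d$flag <- 1
  expect_error(fit_interaction(d, "neutrophils", "fvc", "flag", "age"),
               "constant")
  d$rare <- c(rep(0, 27), 1, 1, 1)
  expect_warning(
    res <- fit_interaction(d, "neutrophils", "fvc", "rare",
                           c("age", "sex", "height", "smoking")),
    "omitted")
  expect_true(is.finite(res$p_interaction))
  expect_false(1 %in% res$strata$level)
})

test_that("sensitivity filters count and remove flagged rows", {
  d <- make_assoc_fixture(n = 10)
  d$cancer <- c(1, 1, rep(0, 8))
  d$anti_infective <- 0
  res <- apply_sensitivity_filter(d, c("cancer", "anti_infective"))
  expect_equal(nrow(res$table), 8)
  expect_equal(unname(res$removed), c(2L, 0L))
  expect_identical(apply_sensitivity_filter(d)$table, d)
  expect_error(apply_sensitivity_filter(d, "no_such_flag"), "no_such_flag")
})
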