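test_that("F statistics and the weak-instrument subset match direct thresholding", {
  expect_equal(compute_f_stat(0.1, 0.01), 100)
  expect_equal(compute_f_stat(0, 0.02), 0)
  set.seed(33)
  bx <- runif(33, 0.01, 0.2)
  sx <- runif(33, 0.005, 0.04)
  instr <- make_instruments(bx, rnorm(33), se_x = sx)
  instr$se_exposure <- sx
  flt <- filter_instruments(instr)
  weak <- instr$snp[(bx / sx)^2 < 10]
  expect_setequal(flt$excluded$snp[flt$excluded$reason == "weak_instrument"],
                  weak)
  expect_setequal(flt$instruments$snp, setdiff(instr$snp, weak))
})

test_that("confounder-associated SNPs are removed at the Bonferroni level", {
  instr <- make_instruments(rep(0.1, 5), rnorm(5), se_x = 0.01)
  conf <- expand.grid(snp = instr$snp,
                      confounder = c("height", "smoking", "alcohol", "exercise"),
                      stringsAsFactors = FALSE)
  conf$p <- 0.5
  cut <- 0.05 / (5 * 4)
  conf$p[conf$snp == "rs002" & conf$confounder == "smoking"] <- cut / 2
  flt <- filter_instruments(instr, confounder_assoc = conf)
  expect_false("rs002" %in% flt$instruments$snp)
  expect_equal(flt$excluded$reason[flt$excluded$snp == "rs002"],
               "confounder_associated")
  # identity when nothing triggers
  conf$p <- 0.5
  flt2 <- filter_instruments(instr, confounder_assoc = conf)
  expect_equal(nrow(flt2$instruments), 5)
  expect_equal(nrow(flt2$excluded), 0)
})

test_that("an empty retained set is an error", {
  instr <- make_instruments(rep(0.001, 4), rnorm(4), se_x = 0.05)  # all weak
  expect_error(filter_instruments(instr), "no instruments")
})

test_that("harmonization flips swapped alleles and flags ambiguous palindromes", {
  ex <- data.frame(snp = c("rs1", "rs2", "rs3", "rs4"),
                   effect_allele = c("A", "A", "A", "C"),
                   other_allele = c("G", "G", "T", "A"),
                   eaf = c(0.3, 0.3, 0.50, 0.3),
                   beta = c(0.1, 0.1, 0.1, 0.1), se = 0.01, p = 1e-8,
                   n = 60000, stringsAsFactors = FALSE)
  ou <- data.frame(snp = c("rs1", "rs2", "rs3", "rs4"),
                   effect_allele = c("G", "A", "A", "T"),
                   other_allele = c("A", "G", "T", "C"),
                   eaf = c(0.7, 0.3, 0.5, 0.3),
                   beta = c(5.0, 5.0, 5.0, 5.0), se = 1, p = 0.01,
                   n = 4000, stringsAsFactors = FALSE)
  h <- harmonize_instruments(ex, ou)
  hi <- h$instruments
  expect_equal(hi$beta_outcome[hi$snp == "rs1"], -5.0)   # swapped -> flipped
  expect_equal(hi$eaf_outcome[hi$snp == "rs1"], 0.3)
  expect_equal(hi$beta_outcome[hi$snp == "rs2"], 5.0)    # identical coding
  expect_true(hi$ambiguous[hi$snp == "rs3"])             # A/T at eaf 0.5
  expect_equal(h$dropped$snp, "rs4")                     # C/A vs G/T mismatch
})

test_that("one-instrument IVW is the Wald ratio and matches a grid-search oracle", {
  one <- make_instruments(0.2, -0.1, se_x = 0.02, se_y = 0.05)
  expect_equal(mr_ivw(one)$estimate, -0.5)

  set.seed(4)
  five <- make_instruments(runif(5, 0.05, 0.2),
                           rnorm(5, -8, 2),
                           se_y = runif(5, 0.5, 2))
  est <- mr_ivw(five)$estimate
  obj <- function(b) sum((five$beta_outcome - b * five$beta_exposure)^2 /
                           five$se_outcome^2)
  grid <- seq(est - 50, est + 50, by = 1e-4)
  expect_lte(obj(est), min(vapply(grid, obj, numeric(1))) + 1e-10)
})

test_that("IVW and Egger are invariant under joint sign flips of a SNP", {
  set.seed(6)
  dat <- make_instruments(runif(8, 0.05, 0.2) * sample(c(-1, 1), 8, TRUE),
                          rnorm(8, 0, 3), se_y = 1)
  flip <- dat
  flip$beta_exposure[3] <- -flip$beta_exposure[3]
  flip$beta_outcome[3] <- -flip$beta_outcome[3]
  expect_equal(mr_ivw(dat)$estimate, mr_ivw(flip)$estimate, tolerance = 1e-12)
  expect_equal(mr_egger(dat)$estimate, mr_egger(flip)$estimate,
               tolerance = 1e-12)
  expect_equal(mr_egger(dat)$egger_intercept, mr_egger(flip)$egger_intercept,
               tolerance = 1e-12)
})

test_that("Egger recovers an exact line and matches a WLS oracle", {
  bx <- c(0.05, 0.08, 0.1, 0.12, 0.15)
  dat <- make_instruments(bx, 0.1 + 0.5 * bx, se_y = 1)
  e <- mr_egger(dat)
  expect_equal(e$egger_intercept, 0.1, tolerance = 1e-10)
  expect_equal(e$estimate, 0.5, tolerance = 1e-10)

  set.seed(9)
  six <- make_instruments(runif(6, 0.05, 0.2), rnorm(6, -5, 2),
                          se_y = runif(6, 0.5, 2))
  e6 <- mr_egger(six)
  fit <- lm(beta_outcome ~ beta_exposure, data = six,
            weights = 1 / six$se_outcome^2)
  expect_equal(e6$estimate, unname(coef(fit)[2]), tolerance = 1e-10)
  expect_equal(e6$egger_intercept, unname(coef(fit)[1]), tolerance = 1e-10)
  # fixed-effect (unscaled) variance: vcov(fit) divided by its sigma^2
  V <- vcov(fit) / summary(fit)$sigma^2
  expect_equal(e6$se, unname(sqrt(V[2, 2])), tolerance = 1e-10)
  expect_equal(e6$intercept_se, unname(sqrt(V[1, 1])), tolerance = 1e-10)
  expect_error(mr_egger(make_instruments(c(0.1, 0.2), c(1, 2))), "at least 3")
})

test_that("PRESSO observed RSS equals a direct leave-one-out loop", {
  set.seed(10)
  six <- make_instruments(runif(6, 0.05, 0.2), rnorm(6, -5, 2),
                          se_x = 0.01, se_y = runif(6, 0.5, 2))
  pr <- mr_presso(six, n_simulations = 200, seed = 1)
  rss_direct <- 0
  for (j in 1:6) {
    sub <- six[-j, ]
    w <- 1 / sub$se_outcome^2
    b_j <- sum(w * sub$beta_exposure * sub$beta_outcome) /
      sum(w * sub$beta_exposure^2)
    rss_direct <- rss_direct +
      (six$beta_outcome[j] - b_j * six$beta_exposure[j])^2 / six$se_outcome[j]^2
  }
  expect_equal(pr$rss_observed, rss_direct, tolerance = 1e-10)
})

test_that("PRESSO is seed-reproducible and validates its inputs", {
  set.seed(11)
  dat <- make_instruments(runif(8, 0.05, 0.2), rnorm(8, -4, 1), se_y = 1)
  a <- mr_presso(dat, n_simulations = 200, seed = 7)
  b <- mr_presso(dat, n_simulations = 200, seed = 7)
  expect_identical(a$global_p, b$global_p)
  expect_identical(a$outlier_p, b$outlier_p)
  expect_error(mr_presso(dat[1:3, ], n_simulations = 200), "at least 4")
  expect_error(mr_presso(dat, n_simulations = 50), "at least 100")
  degen <- make_instruments(rep(0.1, 5), rep(1, 5))
  expect_error(mr_presso(degen, n_simulations = 200), "degenerate")
})

test_that("removing PRESSO outliers moves IVW toward the configured truth", {
  shift <- vapply(1:30, function(s) {
    ts <- generate_two_sample(two_sample_spec(
      n_snps = 21, causal_effect = -100, se_y = 2,
      n_outliers = 1, outlier_magnitude = 20, seed = s))
    pr <- mr_presso(ts$instruments, n_simulations = 1000, seed = s)
    est_all <- pr$ivw_all$estimate
    est_cor <- if (!is.null(pr$ivw_outlier_corrected)) {
      pr$ivw_outlier_corrected$estimate
    } else {
      est_all
    }
    abs(est_all + 100) - abs(est_cor + 100)   # > 0 means correction helped
  }, numeric(1))
  expect_gt(median(shift), 0)
})
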