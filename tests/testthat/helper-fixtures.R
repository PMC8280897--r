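# Fixtures are built in code; no data files.

# Small regression fixture with known structure for normal-equations oracles.
make_assoc_fixture <- function(n = 20, seed = 42) {
  set.seed(seed)
  d <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    age = rnorm(n, 60, 8),
    sex = rbinom(n, 1, 0.5),
    height = rnorm(n, 165, 7),
    smoking = rbinom(n, 1, 0.3),
    neutrophils = rlnorm(n, log(3.2), 0.3),
    fvc = NA_real_
  )
  d$fvc <- 3000 - 30 * d$neutrophils - 20 * d$age + 25 * d$height +
    400 * d$sex + rnorm(n, 0, 200)
  d
}

# Independent OLS oracle: normal equations + classical variance.
ols_oracle <- function(X, y) {
  XtXinv <- solve(crossprod(X))
  beta <- drop(XtXinv %*% crossprod(X, y))
  resid <- y - drop(X %*% beta)
  sigma2 <- sum(resid^2) / (nrow(X) - ncol(X))
  list(beta = setNames(beta, colnames(X)),
       se = setNames(sqrt(sigma2 * diag(XtXinv)), colnames(X)))
}

# Small harmonized instrument table in the canonical column layout.
make_instruments <- function(beta_x, beta_y, se_x = 0.01, se_y = 1,
                             snp = sprintf("rs%03d", seq_along(beta_x))) {
  data.frame(
    snp = snp, chr = 1L, pos = seq_along(beta_x),
    effect_allele = "A", other_allele = "G",
    eaf = 0.3,
    beta_exposure = beta_x, se_exposure = rep_len(se_x, length(beta_x)),
    p_exposure = 2 * pnorm(-abs(beta_x / rep_len(se_x, length(beta_x)))),
    n_exposure = 60000L,
    beta_outcome = beta_y, se_outcome = rep_len(se_y, length(beta_y)),
    p_outcome = 2 * pnorm(-abs(beta_y / rep_len(se_y, length(beta_y)))),
    n_outcome = 4000L,
    stringsAsFactors = FALSE
  )
}

# A minimal cohort spec for fast simulation loops.
small_cohort_spec <- function(n = 300, seed = 1, noise = c(fvc = 400, fev1 = 350),
                              effects = list(fvc = c(wbc_total = -30, age = -20,
                                                     sex = 400, height = 20),
                                             fev1 = c(wbc_total = -20, age = -22,
                                                      sex = 350, height = 16)),
                              interactions = list()) {
  cohort_spec(
    n_subjects = n,
    covariate_means_sds = list(age = c(60, 8), height = c(165, 8)),
    categorical_prevalences = c(sex = 0.5, smoking = 0.4,
                                alcohol = 0.3, exercise = 0.5),
    wbc_means = c(neutrophils = 3.3, lymphocytes = 1.6, monocytes = 0.3),
    wbc_log_sds = c(neutrophils = 0.28, lymphocytes = 0.26, monocytes = 0.3),
    effect_sizes = effects,
    intercepts = c(fvc = 3000, fev1 = 2300),
    interaction_effects = interactions,
    noise_sd = noise,
    seed = seed
  )
}
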