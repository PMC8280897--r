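#' Specify a synthetic cohort
#'
#' Builds the parameter object consumed by [generate_cohort()]. The defaults
#' of the bundled profiles (see [cohort_profile()]) emulate the three cohorts
#' commonly used in WBC/lung-function epidemiology: a US survey population
#' with a complex sampling design and two Chinese occupational/retirement
#' cohorts, one of which reports only a 3-part differential.
#'
#' WBC subtype counts are generated on the log scale from a correlated
#' multivariate Gaussian and exponentiated, which yields the right-skewed
#' marginals seen for eosinophils and basophils. Total WBC is always the sum
#' of the generated subtypes, so the subtype-sum identity holds exactly for
#' every subject.
#'
#' @param n_subjects Number of subjects to generate.
#' @param covariate_means_sds Named list with entries `age` and `height`,
#'   each `c(mean, sd)` (years and cm).
#' @param categorical_prevalences Named numeric vector of proportions in
#'   `[0, 1]` for `sex` (probability of male), `smoking`, `alcohol`,
#'   `exercise`.
#' @param wbc_means Named numeric vector of per-subtype mean counts,
#'   10^9 cells/L. Total WBC is not listed: it is computed as the row sum.
#' @param wbc_log_sds Named numeric vector of log-scale SDs, same names as
#'   `wbc_means`.
#' @param wbc_correlation Symmetric PSD matrix with unit diagonal giving the
#'   log-scale correlation among subtypes (dimnames must match `wbc_means`).
#' @param effect_sizes List with components `fvc` and `fev1`, each a named
#'   numeric vector of slopes in mL per unit of the named column. Names
#'   ending in `_log10` apply the slope to `log10` of the corresponding
#'   count column (the convention used for eosinophils and basophils).
#' @param intercepts Named vector `c(fvc = , fev1 = )`, mL.
#' @param interaction_effects Optional list of entries
#'   `list(outcome =, modifier =, exposure =, delta =)`: an additional slope
#'   `delta` (mL per unit exposure) in the `modifier == 1` stratum.
#' @param noise_sd Named vector `c(fvc = , fev1 = )` of residual SDs, mL.
#' @param residual_cor Correlation between the FVC and FEV1 residuals of a
#'   subject (they share measurement occasion, so it is high).
#' @param fev1_fvc_constraint Logical; enforce `fvc >= fev1 >= 0` by
#'   redrawing the residual pair of violating subjects (max 100 attempts).
#' @param race_probs Optional named probability vector; when present a
#'   multi-level `race` column is generated.
#' @param survey Optional list `list(n_strata =, psus_per_stratum =,
#'   weight_range = c(lo, hi))` describing a stratified-PSU design.
#' @param seed Integer seed; one global seed is expanded into independent
#'   substreams for covariates, counts, noise and survey fields.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [cohort_profile()], [generate_cohort()]
#' @export
cohort_spec <- function(n_subjects,
                        covariate_means_sds = list(age = c(60, 10), height = c(165, 8)),
                        categorical_prevalences = c(sex = 0.5, smoking = 0.3,
                                                    alcohol = 0.3, exercise = 0.5),
                        wbc_means = c(neutrophils = 3.3, lymphocytes = 1.6,
                                      monocytes = 0.28, eosinophils = 0.12,
                                      basophils = 0.08),
                        wbc_log_sds = NULL,
                        wbc_correlation = NULL,
                        effect_sizes = list(fvc = numeric(), fev1 = numeric()),
                        intercepts = c(fvc = 2400, fev1 = 2050),
                        interaction_effects = list(),
                        noise_sd = c(fvc = 450, fev1 = 400),
                        residual_cor = 0.95,
                        fev1_fvc_constraint = TRUE,
                        race_probs = NULL,
                        survey = NULL,
                        seed = 1L) {
  stopifnot(length(n_subjects) == 1, n_subjects >= 1)
  k <- length(wbc_means)
  if (is.null(wbc_log_sds)) {
    wbc_log_sds <- stats::setNames(rep(0.3, k), names(wbc_means))
  }
  if (is.null(wbc_correlation)) {
    wbc_correlation <- matrix(0.25, k, k,
                              dimnames = list(names(wbc_means), names(wbc_means)))
    diag(wbc_correlation) <- 1
  }
  check_psd_correlation(wbc_correlation, "wbc_correlation")
  if (!identical(sort(colnames(wbc_correlation)), sort(names(wbc_means)))) {
    stop("dimnames of wbc_correlation must match names of wbc_means")
  }
  check_probability(categorical_prevalences, "categorical_prevalences")
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0")
  if (any(wbc_means <= 0)) stop("wbc_means must be positive")
  if (abs(residual_cor) > 1) stop("residual_cor must be in [-1, 1]")
  if (!is.null(race_probs)) check_probability(race_probs, "race_probs")
  if (!is.null(survey)) {
    stopifnot(survey$n_strata >= 1, survey$psus_per_stratum >= 1,
              length(survey$weight_range) == 2,
              all(survey$weight_range > 0))
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    covariate_means_sds = covariate_means_sds,
    categorical_prevalences = categorical_prevalences,
    wbc_means = wbc_means,
    wbc_log_sds = wbc_log_sds,
    wbc_correlation = wbc_correlation[names(wbc_means), names(wbc_means)],
    effect_sizes = effect_sizes,
    intercepts = intercepts,
    interaction_effects = interaction_effects,
    noise_sd = noise_sd,
    residual_cor = residual_cor,
    fev1_fvc_constraint = fev1_fvc_constraint,
    race_probs = race_probs,
    survey = survey,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

# Lognormal mean implied by a printed median and (5th, 95th) percentiles.
lognormal_mean_from_quantiles <- function(median, q05, q95) {
  sigma <- (log(q95) - log(q05)) / (2 * stats::qnorm(0.95))
  list(mean = median * exp(sigma^2 / 2), sdlog = sigma)
}

# Expected value of the linear predictor implied by a spec argument list,
# used to back-compute profile intercepts so E[outcome] matches a target
# cohort mean. `_log10` effects use E[log10 X] = (log(mean) - sd^2/2)/ln 10
# for the lognormal counts.
expected_linear_predictor <- function(args, outcome) {
  eff <- args$effect_sizes[[outcome]]
  total <- 0
  for (nm in names(eff)) {
    ev <- if (nm %in% c("age", "height")) {
      args$covariate_means_sds[[nm]][1]
    } else if (nm %in% names(args$categorical_prevalences)) {
      args$categorical_prevalences[[nm]]
    } else if (grepl("_log10$", nm)) {
      col <- sub("_log10$", "", nm)
      (log(args$wbc_means[[col]]) - args$wbc_log_sds[[col]]^2 / 2) / log(10)
    } else {
      args$wbc_means[[nm]]
    }
    total <- total + eff[[nm]] * ev
  }
  total
}

#' Preset cohort profiles
#'
#' Returns a [cohort_spec()] whose marginal summaries emulate one of three
#' study populations: `"nhanes"` (US national survey, 5-part differential,
#' multi-level race, stratified weighted design), `"cow"` (occupational
#' cohort, 3-part differential: neutrophils, lymphocytes, intermediate
#' cells) or `"dftj"` (retirement cohort, 5-part differential). Subtype mean
#' counts follow the published cohort descriptions; eosinophil and basophil
#' means are derived from their printed median and 5th/95th percentiles
#' under a lognormal, and all subtype means are then rescaled
#' proportionally so that their sum equals the published total-WBC mean
#' (the generator defines total WBC as the subtype sum).
#'
#' Lung-function effect sizes default to slopes of the order reported for
#' these cohorts (e.g. roughly -30 mL FVC per 10^9 neutrophils/L); pass
#' `effect_sizes` to override.
#'
#' @param profile One of `"nhanes"`, `"cow"`, `"dftj"`.
#' @param n_subjects Number of subjects (defaults to the published cohort
#'   size).
#' @param seed Integer seed.
#' @param ... Overrides passed on to [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
cohort_profile <- function(profile = c("dftj", "cow", "nhanes"),
                           n_subjects = NULL, seed = 1L, ...) {
  profile <- match.arg(profile)
  if (profile == "dftj") {
    eos <- lognormal_mean_from_quantiles(0.09, 0.03, 0.32)
    bas <- lognormal_mean_from_quantiles(0.06, 0.02, 0.20)
    means <- c(neutrophils = 3.25, lymphocytes = 1.59, monocytes = 0.28,
               eosinophils = eos$mean, basophils = bas$mean)
    means <- means * 5.38 / sum(means)
    sds <- c(neutrophils = 0.30, lymphocytes = 0.28, monocytes = 0.32,
             eosinophils = eos$sdlog, basophils = bas$sdlog)
    args <- list(
      n_subjects = n_subjects %||% 13827L,
      covariate_means_sds = list(age = c(64.40, 8.2), height = c(160.07, 8.2)),
      categorical_prevalences = c(sex = 0.432, smoking = 0.273,
                                  alcohol = 0.309, exercise = 0.902),
      wbc_means = means, wbc_log_sds = sds,
      effect_sizes = list(
        fvc = c(neutrophils = -33, lymphocytes = -12, monocytes = -108,
                eosinophils_log10 = -31, basophils_log10 = -143,
                age = -25, sex = 550, height = 25, smoking = -120,
                alcohol = 10, exercise = 40),
        fev1 = c(neutrophils = -20, lymphocytes = 5, monocytes = -97,
                 eosinophils_log10 = -65, basophils_log10 = -29,
                 age = -28, sex = 480, height = 20, smoking = -140,
                 alcohol = 10, exercise = 40)),
      intercepts = c(fvc = 2422.85, fev1 = 2080.33),
      noise_sd = c(fvc = 430, fev1 = 380),
      seed = seed)
  } else if (profile == "cow") {
    means <- c(neutrophils = 3.60, lymphocytes = 2.18, intermediate_cells = 0.58)
    means <- means * 6.36 / sum(means)
    sds <- c(neutrophils = 0.30, lymphocytes = 0.27, intermediate_cells = 0.35)
    args <- list(
      n_subjects = n_subjects %||% 1762L,
      covariate_means_sds = list(age = c(41.33, 9.2), height = c(170.12, 6.3)),
      categorical_prevalences = c(sex = 0.871, smoking = 0.582,
                                  alcohol = 0.373, exercise = 0.591),
      wbc_means = means, wbc_log_sds = sds,
      effect_sizes = list(
        fvc = c(neutrophils = -26, lymphocytes = -20, intermediate_cells = -80,
                age = -28, sex = 600, height = 30, smoking = -130,
                alcohol = 10, exercise = 40),
        fev1 = c(neutrophils = -18, lymphocytes = -15, intermediate_cells = -60,
                 age = -30, sex = 520, height = 25, smoking = -150,
                 alcohol = 10, exercise = 40)),
      intercepts = c(fvc = 3488.55, fev1 = 3108.48),
      noise_sd = c(fvc = 480, fev1 = 420),
      seed = seed)
  } else {
    eos <- lognormal_mean_from_quantiles(0.16, 0.05, 0.43)
    bas <- lognormal_mean_from_quantiles(0.04, 0.01, 0.13)
    means <- c(neutrophils = 4.12, lymphocytes = 2.04, monocytes = 0.51,
               eosinophils = eos$mean, basophils = bas$mean)
    means <- means * 6.93 / sum(means)
    sds <- c(neutrophils = 0.32, lymphocytes = 0.28, monocytes = 0.32,
             eosinophils = eos$sdlog, basophils = bas$sdlog)
    args <- list(
      n_subjects = n_subjects %||% 3570L,
      covariate_means_sds = list(age = c(45.43, 17), height = c(169.28, 10)),
      categorical_prevalences = c(sex = 0.496, smoking = 0.438,
                                  alcohol = 0.912, exercise = 0.195),
      wbc_means = means, wbc_log_sds = sds,
      effect_sizes = list(
        fvc = c(neutrophils = -20, lymphocytes = -15, monocytes = -314,
                eosinophils_log10 = -150, age = -28, sex = 700, height = 35,
                smoking = -150, alcohol = 20, exercise = 60),
        fev1 = c(neutrophils = -17, lymphocytes = -12, monocytes = -264,
                 eosinophils_log10 = -170, age = -32, sex = 600, height = 28,
                 smoking = -180, alcohol = 20, exercise = 60)),
      intercepts = c(fvc = 4112.97, fev1 = 3207.40),
      noise_sd = c(fvc = 520, fev1 = 470),
      race_probs = c(non_hispanic_white = 0.686, non_hispanic_black = 0.108,
                     mexican_american = 0.074, other_hispanic = 0.061,
                     non_hispanic_asian = 0.044, other_race = 0.027),
      survey = list(n_strata = 14L, psus_per_stratum = 2L,
                    weight_range = c(0.5, 3)),
      seed = seed)
  }
  # the preset "intercepts" hold the published outcome means; back-compute
  # the actual model intercepts so E[fvc], E[fev1] match them
  target_means <- args$intercepts
  override <- list(...)
  args[names(override)] <- override
  if (!"intercepts" %in% names(override)) {
    args$intercepts <- c(
      fvc = unname(target_means[["fvc"]] -
                     expected_linear_predictor(args, "fvc")),
      fev1 = unname(target_means[["fev1"]] -
                      expected_linear_predictor(args, "fev1")))
  }
  do.call(cohort_spec, args)
}

#' Generate an individual-level synthetic cohort
#'
#' Draws covariates, correlated WBC subtype counts and lung-function
#' outcomes according to a [cohort_spec()]. Counts are drawn from a
#' multivariate Gaussian on the log scale (correlation matrix
#' `wbc_correlation`) and exponentiated; subjects whose counts come out
#' non-positive or non-finite are redrawn, never clipped. `wbc_total` is the
#' exact sum of the subtype columns. FVC and FEV1 are linear in the
#' configured covariate and exposure effects (plus any interaction terms)
#' with correlated Gaussian residuals.
#'
#' @param spec A `cohort_spec`.
#' @return A `data.frame` with one row per subject: `subject_id`,
#'   covariates, WBC columns (`wbc_total` plus subtypes), `fvc`, `fev1`, and
#'   `survey_stratum`/`survey_psu`/`survey_weight` when a design is
#'   configured. The spec is attached as attribute `"generator_spec"`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  ids <- sprintf("S%06d", seq_len(n))

  # -- covariates -----------------------------------------------------------
  set.seed(substream_seed(spec$seed, "covariates"))
  cm <- spec$covariate_means_sds
  dat <- data.frame(
    subject_id = ids,
    age = stats::rnorm(n, cm$age[1], cm$age[2]),
    height = stats::rnorm(n, cm$height[1], cm$height[2]),
    stringsAsFactors = FALSE
  )
  pv <- spec$categorical_prevalences
  for (v in names(pv)) dat[[v]] <- stats::rbinom(n, 1L, pv[[v]])
  if (!is.null(spec$race_probs)) {
    dat$race <- sample(names(spec$race_probs), n, replace = TRUE,
                       prob = spec$race_probs)
  }

  # -- WBC counts (lognormal copula; subtype sum defines the total) --------
  set.seed(substream_seed(spec$seed, "counts"))
  sdl <- spec$wbc_log_sds[names(spec$wbc_means)]
  mu <- log(spec$wbc_means) - sdl^2 / 2
  Sigma <- diag(sdl) %*% spec$wbc_correlation %*% diag(sdl)
  counts <- exp(rmvnorm_chol(n, mu, Sigma))
  bad <- which(!is.finite(rowSums(counts)) | apply(counts <= 0, 1, any))
  attempts <- 0L
  while (length(bad) > 0) {
    attempts <- attempts + 1L
    if (attempts > 100L) stop("count resampling failed after 100 attempts")
    counts[bad, ] <- exp(rmvnorm_chol(length(bad), mu, Sigma))
    bad <- bad[!is.finite(rowSums(counts[bad, , drop = FALSE])) |
                 apply(counts[bad, , drop = FALSE] <= 0, 1, any)]
  }
  colnames(counts) <- names(spec$wbc_means)
  dat <- cbind(dat, as.data.frame(counts))
  dat$wbc_total <- rowSums(counts)

  # -- outcomes -------------------------------------------------------------
  lp <- function(outcome) {
    eff <- spec$effect_sizes[[outcome]]
    out <- rep(spec$intercepts[[outcome]], n)
    for (nm in names(eff)) {
      if (grepl("_log10$", nm)) {
        col <- sub("_log10$", "", nm)
        out <- out + eff[[nm]] * log10(dat[[col]])
      } else {
        out <- out + eff[[nm]] * dat[[nm]]
      }
    }
    out
  }
  mu_fvc <- lp("fvc")
  mu_fev1 <- lp("fev1")
  for (ie in spec$interaction_effects) {
    extra <- ie$delta * dat[[ie$exposure]] * dat[[ie$modifier]]
    if (ie$outcome == "fvc") mu_fvc <- mu_fvc + extra else mu_fev1 <- mu_fev1 + extra
  }

  set.seed(substream_seed(spec$seed, "noise"))
  R <- matrix(c(1, spec$residual_cor, spec$residual_cor, 1), 2)
  S <- diag(spec$noise_sd[c("fvc", "fev1")]) %*% R %*%
    diag(spec$noise_sd[c("fvc", "fev1")])
  eps <- rmvnorm_chol(n, c(0, 0), S)
  fvc <- mu_fvc + eps[, 1]
  fev1 <- mu_fev1 + eps[, 2]
  if (spec$fev1_fvc_constraint && any(spec$noise_sd > 0)) {
    bad <- which(fvc < fev1 | fev1 < 0)
    attempts <- 0L
    while (length(bad) > 0) {
      attempts <- attempts + 1L
      if (attempts > 100L) stop("outcome resampling failed after 100 attempts")
      e <- rmvnorm_chol(length(bad), c(0, 0), S)
      fvc[bad] <- mu_fvc[bad] + e[, 1]
      fev1[bad] <- mu_fev1[bad] + e[, 2]
      bad <- bad[fvc[bad] < fev1[bad] | fev1[bad] < 0]
    }
  }
  dat$fvc <- fvc
  dat$fev1 <- fev1

  # -- survey design --------------------------------------------------------
  if (!is.null(spec$survey)) {
    set.seed(substream_seed(spec$seed, "survey"))
    sv <- spec$survey
    perm <- sample.int(n)
    stratum <- rep_len(seq_len(sv$n_strata), n)[order(perm)]
    psu <- rep_len(seq_len(sv$psus_per_stratum), n)[order(sample.int(n))]
    dat$survey_stratum <- stratum
    dat$survey_psu <- psu
    dat$survey_weight <- stats::runif(n, sv$weight_range[1], sv$weight_range[2])
  }

  attr(dat, "generator_spec") <- spec
  dat
}
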