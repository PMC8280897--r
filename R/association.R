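#' Exclude total-WBC outliers
#'
#' Removes subjects whose total WBC count lies more than three standard
#' deviations from the sample mean. Mean and SD are computed once on the
#' full input (single pass, no iteration).
#'
#' @param table A cohort data.frame with a `wbc_total` column.
#' @param n_sd Number of SDs defining the exclusion bounds (default 3).
#' @return A list with `table` (retained rows), `excluded` (data.frame of
#'   removed `subject_id` and `wbc_total`) and `bounds` (`c(lower, upper)`).
#' @export
exclude_wbc_outliers <- function(table, n_sd = 3) {
  if (!"wbc_total" %in% names(table)) stop("wbc_total column is required")
  if (nrow(table) == 0) {
    return(list(table = table,
                excluded = table[0, c("subject_id", "wbc_total"), drop = FALSE],
                bounds = c(lower = NA_real_, upper = NA_real_)))
  }
  m <- mean(table$wbc_total)
  s <- stats::sd(table$wbc_total)
  if (is.na(s) || s == 0) {
    warning("total WBC has zero SD; no outliers excluded")
    return(list(table = table,
                excluded = table[0, c("subject_id", "wbc_total"), drop = FALSE],
                bounds = c(lower = m, upper = m)))
  }
  lower <- m - n_sd * s
  upper <- m + n_sd * s
  out <- table$wbc_total < lower | table$wbc_total > upper
  list(table = table[!out, , drop = FALSE],
       excluded = table[out, c("subject_id", "wbc_total"), drop = FALSE],
       bounds = c(lower = lower, upper = upper))
}

#' Log10-transform right-skewed count columns
#'
#' Adds `<column>_log10` columns for the named counts (by default
#' eosinophils and basophils, whose distributions are right skewed). Zero
#' counts are shifted by an offset equal to half the smallest positive
#' value observed in that column before taking log10; positive counts are
#' transformed as-is. Rows with negative counts are rejected with a
#' warning. All other columns pass through unchanged.
#'
#' @param table Cohort data.frame.
#' @param columns Count columns to transform (absent columns are skipped).
#' @return The table with added `_log10` columns.
#' @export
transform_counts <- function(table, columns = c("eosinophils", "basophils")) {
  for (col in intersect(columns, names(table))) {
    x <- table[[col]]
    neg <- which(x < 0)
    if (length(neg) > 0) {
      warning(length(neg), " row(s) with negative ", col, " rejected")
      table <- table[-neg, , drop = FALSE]
      x <- table[[col]]
    }
    y <- x
    if (any(x == 0)) {
      pos <- x[x > 0]
      if (length(pos) == 0) stop("column ", col, " has no positive values")
      y[x == 0] <- min(pos) / 2
    }
    table[[paste0(col, "_log10")]] <- log10(y)
  }
  table
}

# Build the model frame used by the regression fits: complete cases on the
# used columns; a race covariate is retained only when it has >1 observed
# level (single-race cohorts are not race-adjusted).
assoc_frame <- function(table, vars) {
  vars <- unique(vars)
  missing_cols <- setdiff(vars, names(table))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  d <- table[stats::complete.cases(table[, vars, drop = FALSE]), , drop = FALSE]
  d
}

prune_covariates <- function(d, covariates) {
  keep <- vapply(covariates, function(v) {
    x <- d[[v]]
    length(unique(x[!is.na(x)])) > 1
  }, logical(1))
  covariates[keep]
}

check_full_rank <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    dropped <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  invisible(TRUE)
}

estimate_row <- function(exposure, outcome, beta, se, n_used, model) {
  data.frame(exposure = exposure, outcome = outcome,
             beta = beta, se = se,
             ci_low = beta - Z95 * se, ci_high = beta + Z95 * se,
             p = z_p(beta, se), n_used = n_used, model = model,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Single-marker covariate-adjusted regression
#'
#' Regresses a lung-function outcome (mL) on one WBC exposure with
#' adjustment for covariates. Without a design this is ordinary least
#' squares with model-based variance; with a design it is weighted least
#' squares with stratified-PSU Taylor-linearization (design-based)
#' variance. Confidence intervals use `beta +/- 1.96 * se` and p-values the
#' matching normal reference.
#'
#' @param table Cohort data.frame.
#' @param exposure Name of the exposure column (e.g. `"neutrophils"` or
#'   `"eosinophils_log10"`).
#' @param outcome `"fvc"` or `"fev1"`.
#' @param covariates Character vector of adjustment columns. A `race`
#'   covariate is dropped automatically when it has a single observed level.
#' @param design Optional list `list(stratum =, psu =, weight =)` naming the
#'   survey columns, or `TRUE` for the conventional
#'   `survey_stratum`/`survey_psu`/`survey_weight` names.
#' @return A one-row data.frame (`AssociationEstimate`): `exposure`,
#'   `outcome`, `beta`, `se`, `ci_low`, `ci_high`, `p`, `n_used`, `model`.
#' @export
fit_single_marker <- function(table, exposure, outcome,
                              covariates = character(), design = NULL) {
  if (isTRUE(design)) {
    design <- list(stratum = "survey_stratum", psu = "survey_psu",
                   weight = "survey_weight")
  }
  vars <- c(outcome, exposure, covariates, unlist(design))
  d <- assoc_frame(table, vars)
  covariates <- prune_covariates(d, covariates)
  form <- stats::reformulate(c(exposure, covariates), response = outcome)
  X <- stats::model.matrix(form, d)
  if (nrow(X) <= ncol(X)) stop("too few rows (", nrow(X), ") for ",
                               ncol(X), " parameters")
  check_full_rank(X)
  y <- d[[outcome]]
  if (is.null(design)) {
    fit <- stats::lm.fit(X, y)
    beta <- fit$coefficients[exposure]
    sigma2 <- sum(fit$residuals^2) / fit$df.residual
    XtXinv <- chol2inv(chol(crossprod(X)))
    se <- sqrt(sigma2 * XtXinv[match(exposure, colnames(X)),
                               match(exposure, colnames(X))])
  } else {
    w <- d[[design$weight]]
    if (any(w <= 0)) stop("survey weights must be positive")
    fit <- stats::lm.wfit(X, y, w)
    beta <- fit$coefficients[exposure]
    V <- svy_taylor_vcov(X, fit$residuals, w,
                         d[[design$stratum]], d[[design$psu]])
    se <- sqrt(V[match(exposure, colnames(X)), match(exposure, colnames(X))])
  }
  estimate_row(exposure, outcome, unname(beta), unname(se), nrow(d), "single")
}

#' Effect-modification (interaction) test
#'
#' Fits the covariate-adjusted model with exposure, a binary modifier (sex
#' or smoking) and their cross-product term. `p_interaction` is the Wald
#' p-value of the product term; stratum-specific estimates come from
#' per-stratum refits of the single-marker model.
#'
#' @inheritParams fit_single_marker
#' @param modifier Name of a binary modifier column.
#' @return A list of class `interaction_result`: `exposure`, `outcome`,
#'   `modifier`, `p_interaction`, `interaction_beta`, `interaction_se`, and
#'   `strata` (a data.frame of per-level `AssociationEstimate` rows with a
#'   `level` column).
#' @export
fit_interaction <- function(table, exposure, outcome, modifier,
                            covariates = character()) {
  vars <- c(outcome, exposure, modifier, covariates)
  d <- assoc_frame(table, vars)
  lev <- sort(unique(d[[modifier]]))
  if (length(lev) < 2) stop("modifier '", modifier, "' is constant")
  if (length(lev) > 2) stop("modifier '", modifier, "' must be binary")
  covariates <- prune_covariates(d, setdiff(covariates, modifier))
  prod_col <- paste0(".int_", exposure, "_", modifier)
  d[[prod_col]] <- d[[exposure]] * (d[[modifier]] == lev[2])
  form <- stats::reformulate(c(exposure, modifier, covariates, prod_col),
                             response = outcome)
  X <- stats::model.matrix(form, d)
  check_full_rank(X)
  fit <- stats::lm.fit(X, d[[outcome]])
  sigma2 <- sum(fit$residuals^2) / fit$df.residual
  XtXinv <- chol2inv(chol(crossprod(X)))
  j <- match(prod_col, colnames(X))
  b_int <- fit$coefficients[[prod_col]]
  se_int <- sqrt(sigma2 * XtXinv[j, j])

  strata <- lapply(lev, function(l) {
    sub <- d[d[[modifier]] == l, , drop = FALSE]
    est <- tryCatch(
      fit_single_marker(sub, exposure, outcome, covariates),
      error = function(e) {
        warning("stratum ", modifier, "=", l, " omitted: ",
                conditionMessage(e))
        NULL
      })
    if (!is.null(est)) est$level <- l
    est
  })
  strata <- do.call(rbind, strata[!vapply(strata, is.null, logical(1))])
  structure(list(exposure = exposure, outcome = outcome, modifier = modifier,
                 p_interaction = z_p(b_int, se_int),
                 interaction_beta = b_int, interaction_se = se_int,
                 strata = strata),
            class = "interaction_result")
}

#' Sensitivity-subset filter
#'
#' Removes subjects flagged by any of the named exclusion columns (e.g. a
#' cancer flag or an anti-infectious-drug flag), mirroring sensitivity
#' analyses that re-run the association models on a restricted sample.
#'
#' @param table Cohort data.frame.
#' @param rules Character vector of flag columns; rows where the flag is
#'   `TRUE` (or nonzero) are removed.
#' @return A list with `table` (retained rows) and `removed` (named count of
#'   rows flagged per rule; rows flagged by several rules count in each).
#' @export
apply_sensitivity_filter <- function(table, rules = character()) {
  if (length(rules) == 0) return(list(table = table, removed = integer(0)))
  missing_cols <- setdiff(rules, names(table))
  if (length(missing_cols) > 0) {
    stop("unknown rule column(s): ", paste(missing_cols, collapse = ", "))
  }
  flags <- vapply(rules, function(r) {
    x <- table[[r]]
    !is.na(x) & (as.numeric(x) != 0)
  }, logical(nrow(table)))
  flags <- matrix(flags, nrow = nrow(table))
  drop <- rowSums(flags) > 0
  list(table = table[!drop, , drop = FALSE],
       removed = stats::setNames(colSums(flags), rules))
}
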