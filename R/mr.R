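#' Instrument-strength F statistic
#'
#' Summary-data approximation `F = (beta / se)^2` per SNP. Instruments with
#' `F < 10` are conventionally considered weak.
#'
#' @param beta,se Exposure association and its standard error.
#' @return F statistic(s).
#' @export
compute_f_stat <- function(beta, se) {
  if (any(se <= 0)) stop("se must be positive")
  (beta / se)^2
}

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) COMPLEMENT[a1] == a2

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns outcome effects to the exposure effect allele. SNPs are matched by
#' id; when the outcome's effect allele equals the exposure's other allele
#' the outcome beta is sign-flipped and its frequency reflected; strand
#' flips are resolved by complementing. Palindromic (A/T or C/G) SNPs with
#' exposure effect-allele frequency inside the ambiguity window (0.42,
#' 0.58) are flagged `ambiguous`. SNPs whose allele sets remain incompatible
#' after complementing are dropped and logged.
#'
#' @param exposure,outcome Data.frames with columns `snp`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `p`, `n` (extra columns such as
#'   `chr`/`pos` are carried through from the exposure side).
#' @param ambiguity_window Frequency window flagging palindromic SNPs.
#' @return A list: `instruments` (harmonized data.frame in the canonical
#'   `beta_exposure`/`beta_outcome` layout with logical columns
#'   `palindromic` and `ambiguous`) and `dropped` (data.frame of snp,
#'   reason).
#' @export
harmonize_instruments <- function(exposure, outcome,
                                  ambiguity_window = c(0.42, 0.58)) {
  need <- c("snp", "effect_allele", "other_allele", "eaf", "beta", "se", "p", "n")
  for (nm in c("exposure", "outcome")) {
    d <- get(nm)
    miss <- setdiff(need, names(d))
    if (length(miss) > 0) stop(nm, " table lacks column(s): ",
                               paste(miss, collapse = ", "))
  }
  m <- merge(exposure, outcome, by = "snp", suffixes = c("_x", "_y"))
  up <- function(a) toupper(trimws(a))
  ex_a1 <- up(m$effect_allele_x); ex_a2 <- up(m$other_allele_x)
  ou_a1 <- up(m$effect_allele_y); ou_a2 <- up(m$other_allele_y)
  same <- ou_a1 == ex_a1 & ou_a2 == ex_a2
  swap <- ou_a1 == ex_a2 & ou_a2 == ex_a1
  csame <- COMPLEMENT[ou_a1] == ex_a1 & COMPLEMENT[ou_a2] == ex_a2
  cswap <- COMPLEMENT[ou_a1] == ex_a2 & COMPLEMENT[ou_a2] == ex_a1
  pal <- is_palindromic(ex_a1, ex_a2)
  # for palindromic SNPs strand cannot be told apart: complement-same is
  # same, complement-swap is swap
  keep_as_is <- same | (csame & !pal)
  flip <- (swap | (cswap & !pal)) & !keep_as_is
  ok <- keep_as_is | flip
  dropped <- data.frame(snp = m$snp[!ok],
                        reason = rep("incompatible_alleles", sum(!ok)),
                        stringsAsFactors = FALSE)
  m <- m[ok, , drop = FALSE]
  flip <- flip[ok]
  beta_y <- ifelse(flip, -m$beta_y, m$beta_y)
  eaf_y <- ifelse(flip, 1 - m$eaf_y, m$eaf_y)
  pal <- pal[ok]
  ambiguous <- pal & m$eaf_x > ambiguity_window[1] & m$eaf_x < ambiguity_window[2]
  instruments <- data.frame(
    snp = m$snp,
    effect_allele = up(m$effect_allele_x), other_allele = up(m$other_allele_x),
    eaf = m$eaf_x,
    beta_exposure = m$beta_x, se_exposure = m$se_x,
    p_exposure = m$p_x, n_exposure = m$n_x,
    beta_outcome = beta_y, se_outcome = m$se_y,
    p_outcome = m$p_y, n_outcome = m$n_y,
    eaf_outcome = eaf_y,
    palindromic = pal, ambiguous = ambiguous,
    stringsAsFactors = FALSE
  )
  for (extra in intersect(c("chr", "pos"), names(exposure))) {
    instruments[[extra]] <- exposure[[extra]][match(instruments$snp, exposure$snp)]
  }
  list(instruments = instruments, dropped = dropped)
}

#' Instrument QC filter
#'
#' Applies, in order: the weak-instrument rule (`F < f_min` removed), the
#' confounder-association screen (any confounder p below the
#' Bonferroni-corrected level `alpha / (n_snps * n_confounders)` removes the
#' SNP), removal of palindromic SNPs flagged frequency-ambiguous, and
#' removal of supplied MR-PRESSO outliers. Each removal is logged with its
#' reason.
#'
#' @param instruments Harmonized instrument data.frame (canonical columns).
#' @param confounder_assoc Optional data.frame with columns `snp`,
#'   `confounder`, `p`: one association p-value per (SNP, confounder).
#' @param alpha Base significance level for the Bonferroni screen.
#' @param f_min Weak-instrument threshold on the F statistic.
#' @param presso_outliers Optional character vector of SNP ids flagged by
#'   [mr_presso()].
#' @return A list: `instruments` (retained, with an `f_stat` column) and
#'   `excluded` (data.frame of snp, reason).
#' @export
filter_instruments <- function(instruments, confounder_assoc = NULL,
                               alpha = 0.05, f_min = 10,
                               presso_outliers = NULL) {
  dat <- instruments
  dat$f_stat <- compute_f_stat(dat$beta_exposure, dat$se_exposure)
  log <- data.frame(snp = character(0), reason = character(0),
                    stringsAsFactors = FALSE)
  drop_snps <- function(dat, snps, reason) {
    if (length(snps) == 0) return(list(dat = dat, log = NULL))
    list(dat = dat[!dat$snp %in% snps, , drop = FALSE],
         log = data.frame(snp = snps, reason = reason, stringsAsFactors = FALSE))
  }
  st <- drop_snps(dat, dat$snp[dat$f_stat < f_min], "weak_instrument")
  dat <- st$dat; log <- rbind(log, st$log)
  if (!is.null(confounder_assoc)) {
    stopifnot(all(c("snp", "confounder", "p") %in% names(confounder_assoc)))
    cut <- alpha / (length(unique(confounder_assoc$snp)) *
                      length(unique(confounder_assoc$confounder)))
    bad <- unique(confounder_assoc$snp[confounder_assoc$p < cut])
    st <- drop_snps(dat, intersect(dat$snp, bad), "confounder_associated")
    dat <- st$dat; log <- rbind(log, st$log)
  }
  if ("ambiguous" %in% names(dat)) {
    st <- drop_snps(dat, dat$snp[dat$ambiguous], "palindromic_ambiguous")
    dat <- st$dat; log <- rbind(log, st$log)
  }
  if (!is.null(presso_outliers)) {
    st <- drop_snps(dat, intersect(dat$snp, presso_outliers), "presso_outlier")
    dat <- st$dat; log <- rbind(log, st$log)
  }
  if (nrow(dat) == 0) stop("no instruments retained after filtering")
  list(instruments = dat, excluded = log)
}

mr_result_row <- function(method, estimate, se, n_snps, q_stat, het_p,
                          intercept = NA_real_, intercept_se = NA_real_) {
  data.frame(method = method, estimate = estimate, se = se,
             ci_low = estimate - Z95 * se, ci_high = estimate + Z95 * se,
             p = z_p(estimate, se),
             egger_intercept = intercept, intercept_se = intercept_se,
             intercept_ci_low = intercept - Z95 * intercept_se,
             intercept_ci_high = intercept + Z95 * intercept_se,
             intercept_p = if (is.na(intercept)) NA_real_ else
               z_p(intercept, intercept_se),
             q_stat = q_stat, het_p = het_p, n_snps = n_snps,
             stringsAsFactors = FALSE)
}

#' Inverse-variance-weighted MR estimate
#'
#' The IVW estimate is the weighted through-origin regression of outcome on
#' exposure effects,
#' `sum(bx * by / sy^2) / sum(bx^2 / sy^2)`, with fixed-effect standard
#' error `sqrt(1 / sum(bx^2 / sy^2))` (a multiplicative random-error
#' variant scales the SE by `sqrt(max(1, Q/(n-1)))`). Between-instrument
#' heterogeneity is Cochran's Q over the per-SNP Wald ratios with weights
#' `(sy/bx)^-2`, on `n - 1` df; SNPs with `bx = 0` are excluded from the
#' ratio-based Q with a warning.
#'
#' @param instruments Harmonized instrument data.frame (canonical columns).
#' @param variance `"fixed"` (default) or `"multiplicative"`.
#' @return A one-row data.frame of class `mr_result`.
#' @export
mr_ivw <- function(instruments, variance = c("fixed", "multiplicative")) {
  variance <- match.arg(variance)
  bx <- instruments$beta_exposure
  by <- instruments$beta_outcome
  sy <- instruments$se_outcome
  n <- length(bx)
  if (n < 1) stop("at least one instrument is required")
  if (any(sy <= 0)) stop("se_outcome must be positive")
  w <- 1 / sy^2
  est <- sum(w * bx * by) / sum(w * bx^2)
  se <- sqrt(1 / sum(w * bx^2))
  nz <- bx != 0
  if (!all(nz)) warning(sum(!nz), " SNP(s) with beta_exposure = 0 excluded ",
                        "from the ratio-based heterogeneity statistic")
  q_stat <- het_p <- NA_real_
  if (sum(nz) >= 2) {
    ratio <- by[nz] / bx[nz]
    wq <- (bx[nz] / sy[nz])^2
    q_stat <- sum(wq * (ratio - est)^2)
    het_p <- stats::pchisq(q_stat, df = sum(nz) - 1, lower.tail = FALSE)
  }
  if (variance == "multiplicative" && is.finite(q_stat) && n > 1) {
    se <- se * sqrt(max(1, q_stat / (n - 1)))
  }
  out <- mr_result_row("IVW", est, se, n, q_stat, het_p)
  class(out) <- c("mr_result", "data.frame")
  out
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome effects on exposure effects with a
#' free intercept, weights `1/se_outcome^2`, after re-orienting every SNP so
#' its exposure effect is positive (joint sign flip of `beta_exposure`,
#' `beta_outcome`, required for intercept identifiability). The slope is a
#' pleiotropy-adjusted causal estimate; the intercept estimates average
#' directional pleiotropy. Heterogeneity is the weighted residual sum of
#' squares on `n - 2` df.
#'
#' @inheritParams mr_ivw
#' @return A one-row data.frame of class `mr_result` including
#'   `egger_intercept`, `intercept_se`, `intercept_ci_low`,
#'   `intercept_ci_high`, `intercept_p`.
#' @export
mr_egger <- function(instruments, variance = c("fixed", "multiplicative")) {
  variance <- match.arg(variance)
  n <- nrow(instruments)
  if (n < 3) stop("MR-Egger needs at least 3 instruments")
  s <- sign(instruments$beta_exposure)
  s[s == 0] <- 1
  bx <- abs(instruments$beta_exposure)
  by <- instruments$beta_outcome * s
  sy <- instruments$se_outcome
  if (any(sy <= 0)) stop("se_outcome must be positive")
  w <- 1 / sy^2
  X <- cbind(intercept = 1, slope = bx)
  XtWX <- crossprod(X, X * w)
  coef <- solve(XtWX, crossprod(X, w * by))
  resid <- by - drop(X %*% coef)
  q_stat <- sum(w * resid^2)
  het_p <- stats::pchisq(q_stat, df = n - 2, lower.tail = FALSE)
  V <- solve(XtWX)
  if (variance == "multiplicative") V <- V * max(1, q_stat / (n - 2))
  out <- mr_result_row("Egger", coef["slope", 1], sqrt(V["slope", "slope"]),
                       n, q_stat, het_p,
                       intercept = coef["intercept", 1],
                       intercept_se = sqrt(V["intercept", "intercept"]))
  class(out) <- c("mr_result", "data.frame")
  out
}
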