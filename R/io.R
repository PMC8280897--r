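# Tab-separated UTF-8 with '.' decimal is the interchange format for every
# table the package reads or writes.

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv_raw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty file: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(d) == 0) stop("no data rows in ", path)
  d
}

COHORT_NUMERIC <- c("age", "height", "wbc_total", "neutrophils", "lymphocytes",
                    "monocytes", "eosinophils", "basophils",
                    "intermediate_cells", "fvc", "fev1",
                    "survey_stratum", "survey_psu", "survey_weight",
                    "sex", "smoking", "alcohol", "exercise")
SURVEY_COLS <- c("survey_stratum", "survey_psu", "survey_weight")
COUNT_COLS <- c("wbc_total", "neutrophils", "lymphocytes", "monocytes",
                "eosinophils", "basophils", "intermediate_cells")

#' Write / read a cohort table
#'
#' `write_cohort_table()` writes the tab-separated cohort format;
#' `read_cohort_table()` reads it back with type validation: numeric
#' columns are parsed, rows with malformed numerics or negative counts are
#' rejected (with their line numbers recorded in the `"read_log"`
#' attribute), survey columns must be all present or all absent, and rows
#' with `fvc < fev1` raise a warning.
#'
#' @param table Cohort data.frame.
#' @param path File path.
#' @param mapping Optional named character vector renaming file columns to
#'   the canonical names, e.g. `c(WBC = "wbc_total")`.
#' @return `read_cohort_table()`: the validated data.frame with attribute
#'   `"read_log"` (list with `n_rejected`, `rejected_lines`).
#' @export
write_cohort_table <- function(table, path) write_tsv(table, path)

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path, mapping = NULL) {
  d <- read_tsv_raw(path)
  if (!is.null(mapping)) {
    miss <- setdiff(names(mapping), names(d))
    if (length(miss) > 0) stop("mapped column(s) absent from file: ",
                               paste(miss, collapse = ", "))
    names(d)[match(names(mapping), names(d))] <- unname(mapping)
  }
  bad <- rep(FALSE, nrow(d))
  for (col in intersect(COHORT_NUMERIC, names(d))) {
    x <- suppressWarnings(as.numeric(d[[col]]))
    bad <- bad | (is.na(x) & !is.na(d[[col]]) & trimws(as.character(d[[col]])) != "")
    d[[col]] <- x
  }
  for (col in intersect(COUNT_COLS, names(d))) {
    bad <- bad | (!is.na(d[[col]]) & d[[col]] < 0)
  }
  if (any(bad)) {
    # +1 for the header line
    warning(sum(bad), " malformed row(s) rejected (line ",
            paste(utils::head(which(bad) + 1L, 10), collapse = ", "), ")")
    d <- d[!bad, , drop = FALSE]
  }
  have_survey <- intersect(SURVEY_COLS, names(d))
  if (length(have_survey) > 0 && length(have_survey) < length(SURVEY_COLS)) {
    stop("survey columns must all be present or all absent; found only: ",
         paste(have_survey, collapse = ", "))
  }
  if (all(c("fvc", "fev1") %in% names(d))) {
    n_bad <- sum(d$fvc < d$fev1, na.rm = TRUE)
    if (n_bad > 0) warning(n_bad, " row(s) with fvc < fev1")
  }
  attr(d, "read_log") <- list(n_rejected = sum(bad),
                              rejected_lines = which(bad) + 1L)
  d
}

SUMSTAT_COLS <- c("snp", "chr", "pos", "effect_allele", "other_allele", "eaf",
                  "beta_exposure", "se_exposure", "p_exposure", "n_exposure",
                  "beta_outcome", "se_outcome", "p_outcome", "n_outcome")

#' Write / read two-sample summary statistics
#'
#' The tab-separated layout has columns `snp, chr, pos (1-based),
#' effect_allele, other_allele, eaf, beta_exposure, se_exposure,
#' p_exposure, n_exposure, beta_outcome, se_outcome, p_outcome, n_outcome`.
#' On read, alleles are uppercased, rows with `eaf` outside `[0, 1]` are
#' rejected with a diagnostic, and duplicate SNP ids raise an error.
#'
#' @param stats Instruments data.frame (canonical columns).
#' @param path File path.
#' @return `read_summary_stats()`: the validated data.frame.
#' @export
write_summary_stats <- function(stats, path) write_tsv(stats, path)

#' @rdname write_summary_stats
#' @export
read_summary_stats <- function(path) {
  d <- read_tsv_raw(path)
  miss <- setdiff(SUMSTAT_COLS, names(d))
  if (length(miss) > 0) stop("summary statistics lack column(s): ",
                             paste(miss, collapse = ", "))
  dup <- unique(d$snp[duplicated(d$snp)])
  if (length(dup) > 0) stop("duplicate SNP id(s): ", paste(dup, collapse = ", "))
  d$effect_allele <- toupper(trimws(d$effect_allele))
  d$other_allele <- toupper(trimws(d$other_allele))
  num <- setdiff(SUMSTAT_COLS, c("snp", "effect_allele", "other_allele"))
  for (col in num) d[[col]] <- suppressWarnings(as.numeric(d[[col]]))
  bad <- is.na(d$eaf) | d$eaf < 0 | d$eaf > 1
  if (any(bad)) {
    warning(sum(bad), " row(s) rejected: eaf outside [0, 1] (",
            paste(utils::head(d$snp[bad], 10), collapse = ", "), ")")
    d <- d[!bad, , drop = FALSE]
  }
  if (any(d$se_exposure <= 0, na.rm = TRUE) ||
      any(d$se_outcome <= 0, na.rm = TRUE)) {
    stop("standard errors must be positive")
  }
  d
}

#' Write the truth sidecar of a synthetic two-sample dataset
#'
#' Serializes the ground-truth record (causal effect, planted outlier
#' indices, per-SNP direct effects) as YAML next to the summary statistics.
#'
#' @param truth The `truth` component of a [generate_two_sample()] result.
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  yaml::write_yaml(lapply(truth, function(x) if (is.numeric(x)) as.numeric(x) else x),
                   path)
  invisible(path)
}

#' Read and validate a pipeline configuration
#'
#' Reads the YAML configuration driving [run_pipeline()] and validates it
#' before any computation: referenced files must exist and a `seed` must be
#' present whenever a stochastic stage (LASSO cross-validation or
#' MR-PRESSO) is enabled.
#'
#' @param path YAML file path.
#' @return The validated configuration list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  if (is.null(cfg$outdir)) stop("config must declare an outdir")
  for (co in cfg$cohorts) {
    if (is.null(co$name) || is.null(co$path)) {
      stop("every cohort needs a name and a path")
    }
    if (!file.exists(co$path)) stop("cohort file not found: ", co$path)
  }
  if (!is.null(cfg$mr$summary_stats) && !file.exists(cfg$mr$summary_stats)) {
    stop("summary statistics file not found: ", cfg$mr$summary_stats)
  }
  stochastic <- isTRUE(cfg$mr$presso) || length(cfg$cohorts) > 0
  if (stochastic && is.null(cfg$seed)) {
    stop("config must declare a seed: stochastic stages ",
         "(LASSO cross-validation / MR-PRESSO) are enabled")
  }
  cfg
}
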