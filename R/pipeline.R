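DEFAULT_COVARIATES <- c("age", "sex", "race", "height", "smoking",
                        "alcohol", "exercise")

# Candidate exposures for a cohort: every WBC column present, with the
# right-skewed subtypes on the log10 scale once transform_counts() has run.
wbc_exposures <- function(table) {
  cand <- c("wbc_total", "neutrophils", "lymphocytes", "monocytes",
            "intermediate_cells", "eosinophils_log10", "basophils_log10")
  intersect(cand, names(table))
}

#' Run the full observational + MR pipeline
#'
#' Executes, per cohort: total-WBC outlier exclusion, log10 transform of
#' the right-skewed subtypes, covariate-adjusted single-marker models for
#' each WBC exposure and outcome, LASSO selection of the subtypes with
#' single-marker p < .05 (covariates unpenalized), and the mutually
#' adjusted multiple-marker model. Estimates are then pooled across cohorts
#' by fixed/random-effect meta-analysis. When summary statistics are
#' configured, the MR arm runs instrument QC (F statistic, optional
#' confounder screen), IVW, MR-Egger and MR-PRESSO; PRESSO-flagged outliers
#' are removed and IVW/Egger refitted. All stage tables are written as TSV
#' under `outdir`, together with a YAML run log (package version, seed,
#' parameters) sufficient to re-execute the identical run.
#'
#' @param config Configuration list (see [read_pipeline_config()]) or path
#'   to a YAML file. Recognized fields: `outdir`; `seed`; `cohorts` (list of
#'   `name`, `path`, optional `covariates`, optional `survey` flag);
#'   `outcomes` (default `c("fvc", "fev1")`); `lasso` (`n_folds`);
#'   `meta` (`het_threshold`); `mr` (`summary_stats`, `presso`,
#'   `n_simulations`, `f_min`, `alpha`).
#' @return Invisibly, a list with `single`, `multiple`, `meta` (data.frames),
#'   `mr` (data.frame or NULL), `presso` (list or NULL) and `files` (paths
#'   written).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- validate_pipeline_config(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  outcomes <- config$outcomes %||% c("fvc", "fev1")
  het_threshold <- config$meta$het_threshold %||% 0.05
  files <- character(0)

  single_all <- list()
  multiple_all <- list()
  for (co in config$cohorts) {
    tab <- read_cohort_table(co$path, mapping = co$mapping)
    excl <- exclude_wbc_outliers(tab)
    tab <- transform_counts(excl$table)
    covars <- co$covariates %||% intersect(DEFAULT_COVARIATES, names(tab))
    design <- if (isTRUE(co$survey)) TRUE else NULL
    exposures <- wbc_exposures(tab)
    single <- do.call(rbind, lapply(outcomes, function(oc) {
      do.call(rbind, lapply(exposures, function(ex) {
        fit_single_marker(tab, ex, oc, covars, design = design)
      }))
    }))
    single$cohort <- co$name
    single_all[[co$name]] <- single

    for (oc in outcomes) {
      sub <- single[single$outcome == oc & single$exposure != "wbc_total", ]
      candidates <- sub$exposure[sub$p < 0.05]
      if (length(candidates) == 0) next
      sel <- select_lasso(tab, oc, candidates, setdiff(covars, "race"),
                          config = lasso_config(
                            n_folds = config$lasso$n_folds %||% 10,
                            seed = config$seed))
      if (length(sel$selected) == 0) next
      mm <- fit_multiple_marker(tab, sel$selected, oc, covars)
      mm$cohort <- co$name
      multiple_all[[paste(co$name, oc)]] <- mm
    }
  }
  single_all <- do.call(rbind, single_all)
  multiple_all <- if (length(multiple_all) > 0) do.call(rbind, multiple_all)

  meta_all <- NULL
  if (!is.null(single_all)) {
    combos <- unique(single_all[, c("exposure", "outcome")])
    meta_all <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
      rows <- single_all[single_all$exposure == combos$exposure[i] &
                           single_all$outcome == combos$outcome[i], ]
      m <- pool_estimates(rows$beta, rows$se, het_threshold = het_threshold)
      cbind(combos[i, , drop = FALSE], as.data.frame(m), row.names = NULL)
    }))
  }

  mr_report <- NULL
  presso <- NULL
  if (!is.null(config$mr$summary_stats)) {
    instr <- read_summary_stats(config$mr$summary_stats)
    flt <- filter_instruments(instr,
                              alpha = config$mr$alpha %||% 0.05,
                              f_min = config$mr$f_min %||% 10)
    dat <- flt$instruments
    if (isTRUE(config$mr$presso %||% TRUE) && nrow(dat) >= 4) {
      presso <- mr_presso(dat,
                          n_simulations = config$mr$n_simulations %||% 1000,
                          seed = config$seed)
      if (length(presso$outliers) > 0) {
        flt <- filter_instruments(dat, presso_outliers = presso$outliers)
        dat <- flt$instruments
      }
    }
    mr_report <- rbind(mr_ivw(dat), mr_egger(dat))
    mr_report$global_p <- if (!is.null(presso)) presso$global_p else NA_real_
  }

  # -- outputs --------------------------------------------------------------
  out <- function(name, d) {
    p <- file.path(outdir, name)
    write_tsv(d, p)
    files <<- c(files, p)
  }
  if (!is.null(single_all)) out("single_marker.tsv", single_all)
  if (!is.null(multiple_all)) out("multiple_marker.tsv", multiple_all)
  if (!is.null(meta_all)) out("meta.tsv", meta_all)
  if (!is.null(mr_report)) out("mr.tsv", mr_report)
  log_path <- file.path(outdir, "run_log.yaml")
  yaml::write_yaml(list(package = "wbclung",
                        version = as.character(utils::packageVersion("wbclung")),
                        r_version = paste(R.version$major, R.version$minor, sep = "."),
                        seed = config$seed,
                        config = config), log_path)
  files <- c(files, log_path)
  invisible(list(single = single_all, multiple = multiple_all,
                 meta = meta_all, mr = mr_report, presso = presso,
                 files = files))
}
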