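# Cohort file IO and the end-to-end pipeline driver.

COHORT_COLUMNS <- c("subject_id", "group", "sex", "age", "bmi", "oc_use",
                    FACTOR_NAMES)

#' Read and validate a cohort file
#'
#' The cohort dialect is CSV with header
#' `subject_id,group,sex,age,bmi,oc_use,fII,fV,fVII,fVIII,fIX,fX,AT,TFPI`;
#' `group` is `case` or `control`; missing demographics are empty fields.
#' Validation reports offending line numbers.
#'
#' @param path CSV file path.
#' @return Validated cohort data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(COHORT_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing_column: cohort file lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  lineno <- seq_len(nrow(raw)) + 1L  # header is line 1

  bad_group <- !raw$group %in% c("case", "control")
  if (any(bad_group)) {
    stop("unknown_group: line(s) ",
         paste(lineno[bad_group], collapse = ", "),
         " have group outside {case, control}")
  }
  out <- raw
  for (f in FACTOR_NAMES) {
    v <- suppressWarnings(as.numeric(raw[[f]]))
    bad <- is.na(v) | !is.finite(v)
    if (any(bad)) {
      stop("nonnumeric_factor: column ", f, ", line(s) ",
           paste(lineno[bad], collapse = ", "))
    }
    out[[f]] <- v
  }
  out$age <- suppressWarnings(as.numeric(raw$age))
  out$bmi <- suppressWarnings(as.numeric(raw$bmi))
  out$sex[!out$sex %in% c("M", "F")] <- NA_character_
  out$oc_use <- c("TRUE" = TRUE, "FALSE" = FALSE)[toupper(raw$oc_use)]
  out
}

#' Write a cohort table in the cohort CSV dialect
#'
#' @param cohort Cohort data frame.
#' @param path Output path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort[, COHORT_COLUMNS], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Run the full pipeline: cohort -> metrics -> risk statistics
#'
#' Simulates every subject, computes the pooled percentile cutoffs for
#' MaxR, MaxL and AUC, builds the case-control contingency tables for the
#' whole population and the standard stratifications (sex, OC use among
#' premenopausal women, age at 45 y, BMI at 26 kg/m2), and fits the BMI and
#' age trend slopes within controls. Artifacts are written under `out_dir`:
#' per-subject metrics CSV, contingency CSV, summary JSON and a run
#' manifest.
#'
#' @param cohort Cohort data frame (e.g. from [read_cohort()] or
#'   [sample_case_control_study()]).
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @param config A [sim_config()].
#' @param analyte Analyte for the risk tables.
#' @param q Percentile for the cutoff (default 90).
#' @param mode Validation mode for [run_cohort()].
#' @param progress Passed to [run_cohort()].
#' @return List: `metrics`, `cutoffs`, `contingency` (data frame),
#'   `trends`, `comparisons`, `manifest`.
#' @export
run_all <- function(cohort, out_dir = NULL, config = sim_config(),
                    analyte = "fXa", q = 90, mode = "strict",
                    progress = FALSE) {
  metrics <- run_cohort(cohort, config = config, analytes = analyte,
                        mode = mode, progress = progress)

  cutoffs <- vapply(c("MaxR", "MaxL", "AUC"), function(m) {
    percentile_cutoff(metrics[[m]], q)
  }, numeric(1))

  strata <- list(
    list(label = "whole population", subset = NULL),
    list(label = "men", subset = metrics$sex == "M"),
    list(label = "women", subset = metrics$sex == "F"),
    list(label = "females without OC",
         subset = metrics$sex == "F" & metrics$age <= 49 & !metrics$oc_use),
    list(label = "females with OC",
         subset = metrics$sex == "F" & metrics$age <= 49 & metrics$oc_use),
    list(label = "age <= 45", subset = metrics$age <= 45),
    list(label = "age > 45", subset = metrics$age > 45),
    list(label = "bmi <= 26", subset = metrics$bmi <= 26),
    list(label = "bmi > 26", subset = metrics$bmi > 26)
  )
  rows <- list()
  for (s in strata) {
    for (m in c("MaxR", "MaxL")) {
      ct <- try(prevalence_table(metrics, m, cutoffs[[m]],
                                 subset = s$subset, label = s$label),
                silent = TRUE)
      if (inherits(ct, "try-error")) next  # stratum absent in small cohorts
      rows[[length(rows) + 1]] <- data.frame(
        label = ct$label, metric = ct$metric, cutoff = ct$cutoff,
        a = ct$a, b = ct$b, c = ct$c, d = ct$d,
        case_prevalence = ct$case_prevalence,
        control_prevalence = ct$control_prevalence,
        or = ct$or, ci_low = ct$ci_low, ci_high = ct$ci_high,
        fisher_p = ct$fisher_p, stringsAsFactors = FALSE)
    }
  }
  contingency <- do.call(rbind, rows)

  ctrl <- metrics[metrics$group == "control", ]
  trends <- list(
    maxr_per_bmi = try(linear_trend(ctrl$MaxR, ctrl$bmi), silent = TRUE),
    maxl_per_bmi = try(linear_trend(ctrl$MaxL, ctrl$bmi), silent = TRUE),
    auc_per_bmi = try(linear_trend(ctrl$AUC, ctrl$bmi), silent = TRUE),
    tmaxl_per_age = try(linear_trend(ctrl$TMaxL, ctrl$age), silent = TRUE),
    tmaxr_per_age = try(linear_trend(ctrl$TMaxR, ctrl$age), silent = TRUE)
  )
  trends <- trends[!vapply(trends, inherits, logical(1), "try-error")]

  comparisons <- list(
    case_vs_control_maxr = group_compare(
      metrics$MaxR[metrics$group == "case"],
      metrics$MaxR[metrics$group == "control"])
  )

  manifest <- list(
    n_subjects = nrow(cohort),
    n_simulated = nrow(metrics),
    n_failed = attr(metrics, "n_failed"),
    analyte = analyte, percentile = q,
    seed = attr(cohort, "seed"),
    rng_kind = attr(cohort, "rng_kind"),
    config = unclass(config),
    package_version = as.character(utils::packageVersion("xagen")),
    config_hash = config_hash(config)
  )

  result <- list(metrics = metrics, cutoffs = cutoffs,
                 contingency = contingency, trends = trends,
                 comparisons = comparisons, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(contingency, file.path(out_dir, "contingency.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(cutoffs = as.list(cutoffs), trends = trends,
           comparisons = comparisons),
      file.path(out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA, force = TRUE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  result
}

config_hash <- function(config) {
  s <- paste(names(unclass(config)),
             vapply(unclass(config), format, character(1)),
             collapse = ";")
  # tools' md5 works on files only; hash via a temp file
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(s, tmp)
  unname(tools::md5sum(tmp))
}
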