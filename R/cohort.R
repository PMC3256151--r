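# Cohort-level risk analysis: run the model over every subject, pool the
# generation parameters, and compute 90th-percentile case-control statistics.

#' Simulate every subject of a cohort and extract generation parameters
#'
#' @param cohort Data frame in the cohort dialect (see [read_cohort()]):
#'   columns `subject_id, group, sex, age, bmi, oc_use, fII, ..., TFPI`.
#' @param config A [sim_config()].
#' @param means Mean concentration table.
#' @param analytes Character vector from `c("fXa", "thrombin")`.
#' @param mode `"strict"` aborts on any invalid or failing subject;
#'   `"lenient"` drops them with a warning.
#' @param progress Print a progress line every 100 subjects.
#' @return Data frame, one row per subject x analyte: demographics carried
#'   through plus `MaxR, TMaxR, MaxL, TMaxL, AUC`. The number of excluded
#'   subjects is attached as attribute `n_failed`.
#' @export
run_cohort <- function(cohort, config = sim_config(),
                       means = mean_concentrations(),
                       analytes = "fXa",
                       mode = c("strict", "lenient"),
                       progress = FALSE) {
  mode <- match.arg(mode)
  stopifnot(all(analytes %in% c("fXa", "thrombin")))
  if (nrow(cohort) == 0) {
    out <- cohort[0, c("subject_id", "group", "sex", "age", "bmi", "oc_use")]
    out$analyte <- character(0)
    for (m in c("MaxR", "TMaxR", "MaxL", "TMaxL", "AUC")) out[[m]] <- numeric(0)
    attr(out, "n_failed") <- 0L
    return(out)
  }
  if (anyDuplicated(cohort$subject_id)) {
    dup <- unique(cohort$subject_id[duplicated(cohort$subject_id)])
    warning("duplicate subject_ids: ", paste(dup, collapse = ", "))
  }
  network <- tf_pathway_network(
    include_tf_viia_at = config$include_tf_viia_at)

  rows <- vector("list", nrow(cohort))
  failed <- character(0)
  for (i in seq_len(nrow(cohort))) {
    row <- cohort[i, ]
    res <- try({
      comp <- plasma_composition(
        row$subject_id, row$group,
        fII = row$fII, fV = row$fV, fVII = row$fVII, fVIII = row$fVIII,
        fIX = row$fIX, fX = row$fX, AT = row$AT, TFPI = row$TFPI,
        sex = if (is.null(row$sex)) NA_character_ else row$sex,
        age = if (is.null(row$age)) NA_real_ else row$age,
        bmi = if (is.null(row$bmi)) NA_real_ else row$bmi,
        oc_use = if (is.null(row$oc_use)) NA else row$oc_use)
      traj <- simulate_subject(comp, config, means, network)
      do.call(rbind, lapply(analytes, function(a) {
        met <- trajectory_metrics(traj, a, config)
        cbind(data.frame(subject_id = comp$subject_id, group = comp$group,
                         sex = comp$sex, age = comp$age, bmi = comp$bmi,
                         oc_use = comp$oc_use, stringsAsFactors = FALSE),
              met)
      }))
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      failed <- c(failed, as.character(row$subject_id))
    } else {
      rows[[i]] <- res
    }
    if (progress && i %% 100 == 0) {
      message("simulated ", i, "/", nrow(cohort), " subjects")
    }
  }
  if (length(failed) > 0) {
    msg <- paste0(length(failed), " subject(s) failed validation or ",
                  "simulation: ", paste(utils::head(failed, 10),
                                        collapse = ", "))
    if (mode == "strict") stop("invalid_subjects: ", msg)
    warning(msg)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  attr(out, "n_failed") <- length(failed)
  out
}

#' Nearest-rank percentile cutoff over the pooled population
#'
#' The cutoff below which "above" is decided is the nearest-rank empirical
#' percentile of the pooled cases + controls values: the value at sorted
#' rank `ceiling(q/100 * n)`. "Above the cutoff" always means strictly
#' greater.
#'
#' @param values Pooled metric values.
#' @param q Percentile in (0, 100); default 90.
#' @return The cutoff value.
#' @export
percentile_cutoff <- function(values, q = 90) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 10) stop("too_few_values: need at least 10 pooled values")
  stopifnot(q > 0, q < 100)
  sort(values)[ceiling(q / 100 * n)]
}

#' Case-control contingency counts above a pooled cutoff
#'
#' @param metrics Output of [run_cohort()] filtered to one analyte.
#' @param metric Column name (`"MaxR"`, `"MaxL"` or `"AUC"`).
#' @param cutoff Cutoff computed on the *pooled* population
#'   ([percentile_cutoff()]).
#' @param subset Optional logical vector over rows of `metrics` defining a
#'   subgroup; rows with `NA` are excluded from the subgroup.
#' @param label Subgroup label carried into the result.
#' @return A `contingency_result`: counts `a` (cases above), `b` (cases not
#'   above), `c` (controls above), `d` (controls not above), with the Woolf
#'   odds ratio, its 95% CI and Fisher's exact p attached.
#' @export
prevalence_table <- function(metrics, metric, cutoff, subset = NULL,
                             label = "whole population") {
  stopifnot(metric %in% names(metrics))
  keep <- if (is.null(subset)) rep(TRUE, nrow(metrics)) else !is.na(subset) & subset
  sub <- metrics[keep, ]
  if (nrow(sub) == 0) stop("empty_subgroup: no subjects in subgroup ", label)
  if (!all(c("case", "control") %in% sub$group)) {
    stop("empty_subgroup: subgroup ", label,
         " must contain both cases and controls")
  }
  above <- sub[[metric]] > cutoff
  a <- sum(above & sub$group == "case")
  b <- sum(!above & sub$group == "case")
  cc <- sum(above & sub$group == "control")
  d <- sum(!above & sub$group == "control")
  or <- odds_ratio_ci(a, b, cc, d)
  structure(
    list(label = label, metric = metric, cutoff = cutoff,
         a = a, b = b, c = cc, d = d,
         case_prevalence = a / (a + b),
         control_prevalence = cc / (cc + d),
         or = or$or, ci_low = or$ci_low, ci_high = or$ci_high,
         fisher_p = fisher_exact(a, b, cc, d)),
    class = "contingency_result"
  )
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("%s / %s: a=%d b=%d c=%d d=%d\n",
              x$label, x$metric, x$a, x$b, x$c, x$d))
  if (is.na(x$or)) {
    cat("  OR undefined")
  } else {
    cat(sprintf("  OR %.1f (%.1f-%.1f)", x$or, x$ci_low, x$ci_high))
  }
  cat(sprintf(", Fisher p = %.4g\n", x$fisher_p))
  invisible(x)
}

#' Odds ratio with Woolf (log-normal) 95% confidence interval
#'
#' For a 2x2 table (`a` cases above, `b` cases not above, `c` controls
#' above, `d` controls not above): `OR = (a*d)/(b*c)` and
#' `exp(log(OR) +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`. When any cell is
#' zero the OR is undefined and returned as `NA` (a value, not an error).
#'
#' @param a,b,c,d Non-negative integer counts.
#' @return List with `or`, `ci_low`, `ci_high` (all `NA` when undefined).
#' @export
odds_ratio_ci <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if (a == 0 || b == 0 || c == 0 || d == 0) {
    return(list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_))
  }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = or,
       ci_low = exp(log(or) - 1.96 * se),
       ci_high = exp(log(or) + 1.96 * se))
}

#' Two-sided Fisher's exact p for a 2x2 table
#'
#' @inheritParams odds_ratio_ci
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(a, b, c, d) {
  stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value
}

#' Two-group comparison with normality-gated test choice
#'
#' Each group is checked for normality with a Kolmogorov-Smirnov test
#' against a normal distribution with the sample mean and SD (alpha 0.05).
#' If both pass, a two-sample t-test is used and the difference-of-means
#' 95% CI is reported; otherwise the Wilcoxon rank-sum test.
#'
#' @param values_a,values_b Numeric samples (n >= 3 each).
#' @return List: `test` (`"t"` or `"wilcoxon"`), `statistic`, `p`,
#'   `diff_ci` (length-2, t-test only), and the two KS p-values.
#' @export
group_compare <- function(values_a, values_b) {
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  if (length(values_a) < 3 || length(values_b) < 3) {
    stop("too_few_values: each group needs at least 3 values")
  }
  ks_p <- function(x) {
    if (stats::sd(x) == 0) return(0)  # degenerate: not normal
    suppressWarnings(
      stats::ks.test(x, "pnorm", mean = mean(x), sd = stats::sd(x))$p.value)
  }
  pa <- ks_p(values_a)
  pb <- ks_p(values_b)
  if (pa > 0.05 && pb > 0.05) {
    tt <- stats::t.test(values_a, values_b)
    list(test = "t", statistic = unname(tt$statistic), p = tt$p.value,
         diff_ci = unname(tt$conf.int), ks_p = c(pa, pb))
  } else {
    wt <- suppressWarnings(stats::wilcox.test(values_a, values_b))
    list(test = "wilcoxon", statistic = unname(wt$statistic), p = wt$p.value,
         diff_ci = NULL, ks_p = c(pa, pb))
  }
}

#' Ordinary least-squares trend of a metric on a covariate
#'
#' @param metric Metric values.
#' @param covariate Paired covariate values (e.g. BMI, age); pairs with
#'   missing values are dropped.
#' @return List with `slope`, `ci` (normal-approximation 95% CI) and `n`.
#' @export
linear_trend <- function(metric, covariate) {
  keep <- is.finite(metric) & is.finite(covariate)
  metric <- metric[keep]
  covariate <- covariate[keep]
  if (length(metric) < 10) stop("too_few_values: need at least 10 pairs")
  if (stats::sd(covariate) == 0) {
    stop("zero_variance: covariate has no variance")
  }
  fit <- stats::lm(metric ~ covariate)
  est <- stats::coef(fit)[["covariate"]]
  se <- sqrt(stats::vcov(fit)["covariate", "covariate"])
  list(slope = est, ci = c(est - 1.96 * se, est + 1.96 * se),
       n = length(metric))
}
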