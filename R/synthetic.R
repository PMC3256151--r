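# Synthetic case-control cohorts emulating the published factor-level
# distributions (truncated normal per factor at the printed mean/SD/range).

#' Load a cohort specification
#'
#' The bundled default transcribes the published case-control plasma
#' composition table: per group and factor a mean, SD and observed range
#' (percent of population mean), group sizes 473 controls / 426 cases, and
#' demographic marginals.
#'
#' @param path Optional YAML file; defaults to the bundled spec.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cohort_spec.yaml", package = "xagen")
  }
  spec <- yaml::read_yaml(path)
  for (grp in names(spec$factors)) {
    for (f in names(spec$factors[[grp]])) {
      p <- spec$factors[[grp]][[f]]
      if (!(p$min < p$mean && p$mean < p$max) || p$sd <= 0) {
        stop("invalid distribution for ", grp, "/", f)
      }
    }
  }
  structure(spec, class = "cohort_spec")
}

# Truncated-normal draws by rejection; errors out if the window captures
# almost no mass.
rtruncnorm_reject <- function(n, mean, sd, min, max) {
  if (min >= max) stop("infeasible_truncation: min >= max")
  p_in <- stats::pnorm(max, mean, sd) - stats::pnorm(min, mean, sd)
  if (p_in < 1e-6) {
    stop("infeasible_truncation: truncation window captures ~no mass")
  }
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(ceiling((n - length(out)) / p_in * 1.1) + 8,
                         mean, sd)
    out <- c(out, draw[draw >= min & draw <= max])
  }
  out[seq_len(n)]
}

#' Sample factor levels for one group
#'
#' Draws each factor from a normal distribution truncated at the specified
#' range. Factors are independent by default; a correlation matrix induces
#' dependence through a Gaussian copula (correlated normals mapped through
#' the marginal truncated-normal quantiles by inverse-CDF).
#'
#' @param n Number of individuals.
#' @param factor_params Named list over factors, each
#'   `list(mean, sd, min, max)` in percent.
#' @param correlation Optional 8x8 correlation matrix (factor order
#'   `fII ... TFPI`); default independence.
#' @param mean_overrides Optional named vector replacing selected factor
#'   means (e.g. a subgroup's printed means) while keeping the group SDs
#'   and ranges.
#' @return Data frame of `n` rows with the eight factor columns.
#' @export
sample_factor_levels <- function(n, factor_params, correlation = NULL,
                                 mean_overrides = NULL) {
  stopifnot(setequal(names(factor_params), FACTOR_NAMES))
  if (!is.null(mean_overrides)) {
    for (f in names(mean_overrides)) {
      factor_params[[f]]$mean <- mean_overrides[[f]]
    }
  }
  if (n == 0) {
    out <- as.data.frame(setNames(rep(list(numeric(0)), 8), FACTOR_NAMES))
    return(out)
  }
  if (is.null(correlation)) {
    draws <- lapply(FACTOR_NAMES, function(f) {
      p <- factor_params[[f]]
      rtruncnorm_reject(n, p$mean, p$sd, p$min, p$max)
    })
  } else {
    stopifnot(isSymmetric(correlation), nrow(correlation) == 8)
    if (!requireNamespace("MASS", quietly = TRUE)) {
      stop("the MASS package is required for correlated sampling")
    }
    z <- MASS::mvrnorm(n, mu = rep(0, 8), Sigma = correlation)
    u <- stats::pnorm(z)
    draws <- lapply(seq_along(FACTOR_NAMES), function(i) {
      p <- factor_params[[FACTOR_NAMES[i]]]
      lo <- stats::pnorm(p$min, p$mean, p$sd)
      hi <- stats::pnorm(p$max, p$mean, p$sd)
      stats::qnorm(lo + u[, i] * (hi - lo), p$mean, p$sd)
    })
  }
  setNames(as.data.frame(draws), FACTOR_NAMES)
}

sample_demographics <- function(n, demo, group) {
  sex <- ifelse(stats::runif(n) < demo$p_female, "F", "M")
  age <- rtruncnorm_reject(n, demo$age$mean, demo$age$sd,
                           demo$age$min, demo$age$max)
  bmi <- rtruncnorm_reject(n, demo$bmi$mean, demo$bmi$sd,
                           demo$bmi$min, demo$bmi$max)
  premeno <- sex == "F" & age <= 49
  oc <- rep(FALSE, n)
  oc[premeno] <- stats::runif(sum(premeno)) <
    demo$p_oc_given_premenopausal_female
  data.frame(sex = sex, age = round(age, 1), bmi = round(bmi, 1),
             oc_use = oc, stringsAsFactors = FALSE)
}

#' Sample a single-group cohort
#'
#' @param spec A [cohort_spec()].
#' @param group `"control"` or `"case"`.
#' @param n Group size; defaults to the spec's size.
#' @param seed Integer seed; the generator (Mersenne-Twister via
#'   `set.seed`) and seed are recorded in attributes for reproducibility.
#' @param correlation,mean_overrides Passed to [sample_factor_levels()].
#' @return Cohort data frame in the dialect of [read_cohort()].
#' @export
sample_cohort <- function(spec = cohort_spec(), group = "control",
                          n = NULL, seed = 1L, correlation = NULL,
                          mean_overrides = NULL) {
  stopifnot(group %in% names(spec$factors))
  if (is.null(n)) n <- spec$group_sizes[[group]]
  set.seed(seed, kind = "Mersenne-Twister")
  levels <- sample_factor_levels(n, spec$factors[[group]], correlation,
                                 mean_overrides)
  demo <- if (n > 0) {
    sample_demographics(n, spec$demographics[[group]], group)
  } else {
    data.frame(sex = character(0), age = numeric(0), bmi = numeric(0),
               oc_use = logical(0))
  }
  out <- cbind(
    data.frame(
      subject_id = if (n > 0) sprintf("%s_%04d", group, seq_len(n))
                   else character(0),
      group = rep(group, n), stringsAsFactors = FALSE),
    demo, round(levels, 1))
  attr(out, "seed") <- seed
  attr(out, "rng_kind") <- "Mersenne-Twister"
  out
}

#' Sample a full case-control study
#'
#' Controls and cases are drawn from their respective factor distributions
#' (defaults: the published control and case rows) with demographics from
#' the configured marginals; default sizes 473 controls and 426 cases.
#'
#' @inheritParams sample_cohort
#' @param n_control,n_case Group sizes; default to the spec.
#' @param null_effect If `TRUE`, cases are drawn from the *control*
#'   distributions (a null cohort by construction).
#' @return Combined cohort data frame (controls first).
#' @export
sample_case_control_study <- function(spec = cohort_spec(), seed = 1L,
                                      n_control = NULL, n_case = NULL,
                                      correlation = NULL,
                                      null_effect = FALSE) {
  if (is.null(n_control)) n_control <- spec$group_sizes$control
  if (is.null(n_case)) n_case <- spec$group_sizes$case
  controls <- sample_cohort(spec, "control", n_control, seed = seed,
                            correlation = correlation)
  case_spec <- spec
  if (null_effect) case_spec$factors$case <- spec$factors$control
  cases <- sample_cohort(case_spec, "case", n_case, seed = seed + 1L,
                         correlation = correlation)
  out <- rbind(controls, cases)
  attr(out, "seed") <- seed
  attr(out, "rng_kind") <- "Mersenne-Twister"
  out
}
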