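# Plasma compositions: an individual's eight measured factor levels,
# expressed as percent of the population mean (100 = mean), plus optional
# demographics used by the risk analyses.

FACTOR_NAMES <- c("fII", "fV", "fVII", "fVIII", "fIX", "fX", "AT", "TFPI")

#' An individual's plasma factor composition
#'
#' @param subject_id Identifier string.
#' @param group `"case"` or `"control"`.
#' @param fII,fV,fVII,fVIII,fIX,fX,AT,TFPI Factor levels in percent of the
#'   population mean (dimensionless; 100 = mean). All must be finite and
#'   non-negative.
#' @param sex Optional `"M"` or `"F"`.
#' @param age Optional age in years.
#' @param bmi Optional body mass index in kg/m^2.
#' @param oc_use Optional logical flag for oral contraceptive use.
#' @return A `plasma_composition` object (named list).
#' @export
plasma_composition <- function(subject_id, group = c("control", "case"),
                               fII, fV, fVII, fVIII, fIX, fX, AT, TFPI,
                               sex = NA_character_, age = NA_real_,
                               bmi = NA_real_, oc_use = NA) {
  group <- match.arg(group)
  levels <- c(fII = fII, fV = fV, fVII = fVII, fVIII = fVIII,
              fIX = fIX, fX = fX, AT = AT, TFPI = TFPI)
  validate_factor_levels(levels, subject_id)
  if (!is.na(sex) && !sex %in% c("M", "F")) {
    stop("sex must be 'M', 'F' or NA")
  }
  structure(
    list(subject_id = as.character(subject_id), group = group,
         levels = levels, sex = sex, age = as.numeric(age),
         bmi = as.numeric(bmi), oc_use = oc_use),
    class = "plasma_composition"
  )
}

validate_factor_levels <- function(levels, subject_id = "<unknown>") {
  if (!identical(names(levels), FACTOR_NAMES)) {
    missing <- setdiff(FACTOR_NAMES, names(levels))
    stop("missing_factor: subject ", subject_id,
         " lacks factor level(s): ", paste(missing, collapse = ", "))
  }
  if (any(!is.finite(levels))) {
    stop("nonfinite_factor_level: subject ", subject_id,
         " has non-finite factor level(s)")
  }
  if (any(levels < 0)) {
    stop("negative_factor_level: subject ", subject_id,
         " has negative factor level(s): ",
         paste(names(levels)[levels < 0], collapse = ", "))
  }
  invisible(levels)
}

#' @export
print.plasma_composition <- function(x, ...) {
  cat("Plasma composition", x$subject_id, sprintf("(%s)\n", x$group))
  print(round(x$levels, 1))
  invisible(x)
}

#' Mean plasma concentrations defining the 100% level
#'
#' Loads the molar concentration corresponding to a 100% level for each of
#' the eight factors. Defaults ship with prothrombin at 1.4 uM and fX at
#' 170 nM; any entry can be overridden.
#'
#' @param path Optional YAML file overriding the bundled table.
#' @param overrides Optional named numeric vector of replacements (mol/L).
#' @return Named numeric vector (mol/L) over `fII, fV, ..., TFPI`.
#' @export
mean_concentrations <- function(path = NULL, overrides = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "mean_concentrations.yaml",
                        package = "xagen")
  }
  tab <- vapply(yaml::read_yaml(path), as.numeric, numeric(1))
  if (!is.null(overrides)) tab[names(overrides)] <- overrides
  missing <- setdiff(FACTOR_NAMES, names(tab))
  if (length(missing) > 0) {
    stop("mean concentration table incomplete: ",
         paste(missing, collapse = ", "))
  }
  tab <- tab[FACTOR_NAMES]
  if (any(!is.finite(tab)) || any(tab <= 0)) {
    stop("mean concentrations must be finite and strictly positive")
  }
  tab
}

#' Convert percent-of-mean factor levels to molar concentrations
#'
#' @param composition A [plasma_composition()] (or bare named vector of the
#'   eight percent levels).
#' @param means Mean concentration table from [mean_concentrations()].
#' @return Named numeric vector of molar concentrations (mol/L).
#' @export
percent_to_molar <- function(composition, means = mean_concentrations()) {
  levels <- if (inherits(composition, "plasma_composition")) {
    composition$levels
  } else {
    validate_factor_levels(composition[FACTOR_NAMES])
  }
  (levels / 100) * means[names(levels)]
}

#' Published reference compositions
#'
#' The individual compositions and oral-contraceptive subgroup mean
#' compositions printed with the study: two control individuals whose
#' simulated thrombin curves overlap but whose factor Xa curves separate,
#' and the mean compositions of oral contraceptive users and non-users
#' among premenopausal control women.
#'
#' @return Named list of four `plasma_composition` objects:
#'   `individual_1`, `individual_2`, `oc_users`, `oc_nonusers`.
#' @export
fixture_compositions <- function() {
  list(
    individual_1 = plasma_composition(
      "individual_1", "control",
      fII = 97, fV = 89, fVII = 157, fVIII = 137,
      fIX = 87, fX = 134, AT = 99, TFPI = 64, sex = "F"),
    individual_2 = plasma_composition(
      "individual_2", "control",
      fII = 97, fV = 164, fVII = 131, fVIII = 188,
      fIX = 100, fX = 124, AT = 101, TFPI = 87, sex = "F"),
    oc_users = plasma_composition(
      "oc_users", "control",
      fII = 106, fV = 112, fVII = 118, fVIII = 124,
      fIX = 115, fX = 118, AT = 95, TFPI = 68,
      sex = "F", oc_use = TRUE),
    oc_nonusers = plasma_composition(
      "oc_nonusers", "control",
      fII = 102, fV = 123, fVII = 104, fVIII = 117,
      fIX = 92, fX = 96, AT = 100, TFPI = 86,
      sex = "F", oc_use = FALSE)
  )
}
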