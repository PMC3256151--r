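# Which factors drive the difference between two groups' generation curves,
# and what is the minimal subset whose adjustment normalizes the output?

#' Discrepancy between two generation curves
#'
#' Dimensionless worst-case relative difference of the three magnitude
#' parameters: `max over {MaxL, MaxR, AUC} of |m_A - m_B| / m_B`. A curve is
#' considered normalized to the reference when the discrepancy is at most
#' `theta` (default 0.05).
#'
#' @param series_a,series_b Analyte concentration series on the same uniform
#'   grid (mol/L); `series_b` is the reference.
#' @param step Grid step in seconds.
#' @return The discrepancy (>= 0).
#' @export
curve_discrepancy <- function(series_a, series_b, step = 1) {
  if (length(series_a) != length(series_b)) {
    stop("series must share one grid")
  }
  ma <- extract_metrics(series_a, step = step)
  mb <- extract_metrics(series_b, step = step)
  ref <- c(mb$MaxL, mb$MaxR, mb$AUC)
  if (any(ref == 0)) {
    stop("zero_reference: reference metrics must be nonzero")
  }
  max(abs(c(ma$MaxL, ma$MaxR, ma$AUC) - ref) / ref)
}

adjust_composition <- function(base, reference, factors) {
  unknown <- setdiff(factors, FACTOR_NAMES)
  if (length(unknown) > 0) {
    stop("unknown_factor: ", paste(unknown, collapse = ", "))
  }
  adj <- base
  adj$levels[factors] <- reference$levels[factors]
  adj$subject_id <- paste0(base$subject_id, "+adj")
  adj
}

sim_series <- function(composition, analyte, config, means, network) {
  traj <- simulate_subject(composition, config, means, network)
  analyte_series(traj, analyte, config)
}

#' Discrepancy reduction from adjusting a single factor
#'
#' Sets one factor of the base composition to the reference group's value,
#' re-simulates, and reports the discrepancy to the reference curve before
#' and after the adjustment.
#'
#' @param base,reference [plasma_composition()] objects (e.g. group mean
#'   compositions).
#' @param factor One of `fII, fV, fVII, fVIII, fIX, fX, AT, TFPI`.
#' @param analyte `"fXa"` or `"thrombin"`.
#' @param config,means,network Simulation settings as in
#'   [simulate_subject()].
#' @return List with `factor`, `before`, `after` and `reduction`
#'   (`before - after`).
#' @export
single_factor_effect <- function(base, reference, factor,
                                 analyte = c("fXa", "thrombin"),
                                 config = sim_config(),
                                 means = mean_concentrations(),
                                 network = NULL) {
  analyte <- match.arg(analyte)
  if (is.null(network)) {
    network <- tf_pathway_network(
      include_tf_viia_at = config$include_tf_viia_at)
  }
  step <- config$output_grid_step
  ref_series <- sim_series(reference, analyte, config, means, network)
  before <- curve_discrepancy(
    sim_series(base, analyte, config, means, network), ref_series, step)
  after <- curve_discrepancy(
    sim_series(adjust_composition(base, reference, factor),
               analyte, config, means, network),
    ref_series, step)
  list(factor = factor, before = before, after = after,
       reduction = before - after)
}

#' Minimal factor subset normalizing one group's curve to another's
#'
#' Exhaustive search over all subsets of the eight factors by increasing
#' cardinality: for each subset, the base composition is re-simulated with
#' those factors set to the reference values and the curve discrepancy to
#' the reference is measured. The smallest subset achieving discrepancy
#' `<= theta` is returned (ties at equal size broken by smallest
#' discrepancy), together with the full per-subset trace.
#'
#' @inheritParams single_factor_effect
#' @param theta Normalization threshold on the discrepancy (default 0.05).
#' @return List: `subset` (character vector, possibly empty), `discrepancy`,
#'   `baseline` (unadjusted discrepancy), and `trace` (data frame of every
#'   evaluated subset with its size and discrepancy, in evaluation order).
#'   If no subset - including all eight factors - reaches `theta`, an error
#'   carrying the best achieved value is thrown.
#' @export
normalization_search <- function(base, reference,
                                 analyte = c("fXa", "thrombin"),
                                 theta = 0.05,
                                 config = sim_config(),
                                 means = mean_concentrations(),
                                 network = NULL) {
  analyte <- match.arg(analyte)
  stopifnot(theta > 0)
  if (is.null(network)) {
    network <- tf_pathway_network(
      include_tf_viia_at = config$include_tf_viia_at)
  }
  step <- config$output_grid_step
  ref_series <- sim_series(reference, analyte, config, means, network)

  subsets <- list(character(0))
  for (size in 1:8) {
    cmb <- utils::combn(FACTOR_NAMES, size, simplify = FALSE)
    subsets <- c(subsets, cmb)
  }
  sizes <- lengths(subsets)
  disc <- numeric(length(subsets))
  cache_base <- sim_series(base, analyte, config, means, network)
  for (i in seq_along(subsets)) {
    series <- if (sizes[i] == 0) {
      cache_base
    } else {
      sim_series(adjust_composition(base, reference, subsets[[i]]),
                 analyte, config, means, network)
    }
    disc[i] <- curve_discrepancy(series, ref_series, step)
  }
  trace <- data.frame(
    subset = vapply(subsets, paste, character(1), collapse = "+"),
    size = sizes, discrepancy = disc, stringsAsFactors = FALSE)

  pass <- which(disc <= theta)
  if (length(pass) == 0) {
    stop("no_normalizing_subset: best discrepancy ", format(min(disc)),
         " exceeds theta = ", theta)
  }
  best_size <- min(sizes[pass])
  at_size <- pass[sizes[pass] == best_size]
  winner <- at_size[which.min(disc[at_size])]
  list(subset = subsets[[winner]], discrepancy = disc[winner],
       baseline = disc[1], theta = theta, trace = trace)
}
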