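# Reduction of species trajectories to generation-curve parameters.

#' Total active factor Xa of a state or trajectory
#'
#' Total active fXa is free fXa plus fXa resident in prothrombinase,
#' including substrate-bound prothrombinase: `Xa + Xa:Va + Xa:Va:II`.
#' Inhibited fXa (Xa:TFPI, Xa:AT, TF:VIIa:Xa and its TFPI complex) is
#' excluded, as is fXa held in the TF:VIIa:Xa product complex.
#'
#' @param state Named vector of species concentrations, or a trajectory data
#'   frame (then a per-grid-point series is returned).
#' @param include_xa_va_ii Count the substrate-bound prothrombinase complex
#'   (default `TRUE`).
#' @return Concentration (mol/L), scalar or series.
#' @export
total_active_fxa <- function(state, include_xa_va_ii = TRUE) {
  cols <- c("Xa", "Xa_Va", if (include_xa_va_ii) "Xa_Va_II")
  if (is.data.frame(state)) {
    rowSums(state[, cols, drop = FALSE])
  } else {
    sum(state[cols])
  }
}

#' Total thrombin of a state or trajectory
#'
#' Thrombin plus weighted meizothrombin, `IIa + w * mIIa`; the default
#' weight 1.2 follows the source model's convention for meizothrombin's
#' relative activity.
#'
#' @inheritParams total_active_fxa
#' @param meizothrombin_weight Non-negative weight `w`.
#' @return Concentration (mol/L), scalar or series.
#' @export
total_thrombin <- function(state, meizothrombin_weight = 1.2) {
  stopifnot(meizothrombin_weight >= 0)
  if (is.data.frame(state)) {
    state[["IIa"]] + meizothrombin_weight * state[["mIIa"]]
  } else {
    unname(state["IIa"] + meizothrombin_weight * state["mIIa"])
  }
}

#' Extract generation-curve parameters from a concentration series
#'
#' Computes the five generation parameters on a uniform time grid:
#' maximum level `MaxL` and earliest time attaining it `TMaxL`; maximum rate
#' `MaxR` from the discrete forward difference `(s[i+1] - s[i]) / step`
#' (assigned to the later grid point) and its earliest time `TMaxR`; and
#' `AUC` as the rectangle sum `sum(series) * step`.
#'
#' @param series Numeric concentration series (mol/L) on a uniform grid.
#' @param step Grid step in seconds (default 1).
#' @param times Optional explicit time grid; must be uniform.
#' @param analyte `"fXa"` or `"thrombin"`; sets the reporting units:
#'   fXa in nM (MaxL), pM/s (MaxR) and uM*s (AUC); thrombin in nM, nM/s
#'   and uM*s.
#' @return A one-row data frame with columns `analyte, MaxR, TMaxR, MaxL,
#'   TMaxL, AUC` in reporting units.
#' @export
extract_metrics <- function(series, step = 1, times = NULL,
                            analyte = c("fXa", "thrombin")) {
  analyte <- match.arg(analyte)
  if (!is.null(times)) {
    if (length(times) != length(series)) {
      stop("times and series lengths differ")
    }
    d <- diff(times)
    if (length(d) == 0 || any(abs(d - d[1]) > 1e-9 * max(1, abs(d[1])))) {
      stop("nonuniform_grid: time grid must be uniform")
    }
    step <- d[1]
    t0 <- times[1]
  } else {
    t0 <- 0
  }
  if (length(series) < 2) stop("series must have at least 2 points")
  if (any(!is.finite(series))) stop("series must be finite")

  # earliest attainment, with ties called at ~1e-9 relative resolution so
  # floating-point noise on flat stretches cannot push the time later
  earliest_max <- function(x) which(x >= max(x) - 1e-9 * abs(max(x)))[1]

  max_l <- max(series)
  t_max_l <- t0 + (earliest_max(series) - 1) * step

  rate <- diff(series) / step         # assigned to the later endpoint
  max_r <- max(rate)
  t_max_r <- t0 + earliest_max(rate) * step

  auc <- sum(series) * step

  scale <- switch(analyte,
    fXa = c(level = 1e9, rate = 1e12, auc = 1e6),       # nM, pM/s, uM*s
    thrombin = c(level = 1e9, rate = 1e9, auc = 1e6))   # nM, nM/s, uM*s

  data.frame(analyte = analyte,
             MaxR = max_r * scale[["rate"]],
             TMaxR = t_max_r,
             MaxL = max_l * scale[["level"]],
             TMaxL = t_max_l,
             AUC = auc * scale[["auc"]],
             stringsAsFactors = FALSE)
}

#' Generation parameters of a simulated trajectory
#'
#' Convenience wrapper: pulls the analyte series out of a trajectory and
#' calls [extract_metrics()].
#'
#' @param trajectory A trajectory from [simulate_subject()].
#' @param analyte `"fXa"` or `"thrombin"`.
#' @param config A [sim_config()] (for the meizothrombin weight and the
#'   prothrombinase counting convention).
#' @return One-row data frame of generation parameters.
#' @export
trajectory_metrics <- function(trajectory, analyte = c("fXa", "thrombin"),
                               config = sim_config()) {
  analyte <- match.arg(analyte)
  series <- analyte_series(trajectory, analyte, config)
  extract_metrics(series, times = trajectory$time, analyte = analyte)
}

#' @rdname trajectory_metrics
#' @export
analyte_series <- function(trajectory, analyte = c("fXa", "thrombin"),
                           config = sim_config()) {
  analyte <- match.arg(analyte)
  switch(analyte,
    fXa = total_active_fxa(trajectory, config$include_xa_va_ii),
    thrombin = total_thrombin(trajectory, config$meizothrombin_weight))
}
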