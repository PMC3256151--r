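# Simulation of the tissue factor pathway from a plasma composition.

#' Simulation configuration
#'
#' @param tf_concentration Tissue factor trigger in mol/L (default 5 pM).
#' @param fviia_fraction_of_fvii Fraction of the individual's molar fVII
#'   circulating as fVIIa (default 0.01, i.e. 1%).
#' @param t_end Integration horizon in seconds (default 3600).
#' @param output_grid_step Output sampling step in seconds (default 1; the
#'   grid is closed, `t = 0, step, ..., t_end`).
#' @param rtol,atol Relative / absolute solver tolerances (mol/L for `atol`).
#' @param include_tf_viia_at Keep the TF:VIIa + AT inhibition reaction.
#' @param meizothrombin_weight Weight of meizothrombin in the reported
#'   "total thrombin" (see [total_thrombin()]).
#' @param include_xa_va_ii Count substrate-bound prothrombinase in
#'   "total active fXa" (see [total_active_fxa()]).
#' @return A `sim_config` list.
#' @export
sim_config <- function(tf_concentration = 5e-12,
                       fviia_fraction_of_fvii = 0.01,
                       t_end = 3600,
                       output_grid_step = 1,
                       rtol = 1e-8,
                       atol = 1e-14,
                       include_tf_viia_at = TRUE,
                       meizothrombin_weight = 1.2,
                       include_xa_va_ii = TRUE) {
  stopifnot(t_end > 0, output_grid_step > 0, rtol > 0, atol > 0,
            tf_concentration >= 0, fviia_fraction_of_fvii >= 0)
  structure(
    list(tf_concentration = tf_concentration,
         fviia_fraction_of_fvii = fviia_fraction_of_fvii,
         t_end = t_end, output_grid_step = output_grid_step,
         rtol = rtol, atol = atol,
         include_tf_viia_at = include_tf_viia_at,
         meizothrombin_weight = meizothrombin_weight,
         include_xa_va_ii = include_xa_va_ii),
    class = "sim_config"
  )
}

#' Initial species state for an individual
#'
#' Zymogens (fII, fV, fVII, fVIII, fIX, fX) and inhibitors (TFPI, AT) start
#' at the individual's molar levels; circulating fVIIa is set to a fixed
#' fraction (default 1%) of that individual's molar fVII; tissue factor is
#' the configured trigger; every enzyme, activated cofactor and complex
#' starts at zero.
#'
#' @inheritParams percent_to_molar
#' @param config A [sim_config()].
#' @return Named numeric vector over all network species (mol/L).
#' @export
build_initial_state <- function(composition,
                                means = mean_concentrations(),
                                config = sim_config()) {
  molar <- percent_to_molar(composition, means)
  y <- setNames(numeric(length(TF_PATHWAY_SPECIES)), TF_PATHWAY_SPECIES)
  y["TF"] <- config$tf_concentration
  y["II"] <- molar[["fII"]]
  y["V"] <- molar[["fV"]]
  y["VII"] <- molar[["fVII"]]
  y["VIIa"] <- config$fviia_fraction_of_fvii * molar[["fVII"]]
  y["VIII"] <- molar[["fVIII"]]
  y["IX"] <- molar[["fIX"]]
  y["X"] <- molar[["fX"]]
  y["TFPI"] <- molar[["TFPI"]]
  y["AT"] <- molar[["AT"]]
  y
}

#' Integrate the tissue factor pathway for one individual
#'
#' Stiff adaptive integration (lsoda, compiled mass-action right-hand side)
#' of the reaction network from the individual's initial state over the
#' configured horizon, sampled on the uniform output grid. Small negative
#' concentrations within solver tolerance are clamped to zero in the
#' returned trajectory only.
#'
#' @inheritParams build_initial_state
#' @param network A [tf_pathway_network()]; built from `config` if `NULL`.
#' @return A `trajectory`: data frame with `time` (s) and one column per
#'   species (mol/L), with the subject id and config attached as attributes.
#' @export
simulate_subject <- function(composition,
                             config = sim_config(),
                             means = mean_concentrations(),
                             network = NULL) {
  if (is.null(network)) {
    network <- tf_pathway_network(
      include_tf_viia_at = config$include_tf_viia_at)
  }
  y0 <- build_initial_state(composition, means, config)
  times <- seq(0, config$t_end, by = config$output_grid_step)
  parms <- encode_network(network)
  subject_id <- if (inherits(composition, "plasma_composition")) {
    composition$subject_id
  } else {
    "<anonymous>"
  }

  out <- try(deSolve::lsoda(
    y = y0, times = times, func = "xagen_derivs", parms = parms,
    dllname = "xagen", initfunc = "xagen_initmod",
    rtol = config$rtol, atol = config$atol, maxsteps = 50000
  ), silent = TRUE)
  if (inherits(out, "try-error") || nrow(out) < length(times)) {
    stop("solver_failure: integration failed for subject ", subject_id)
  }

  traj <- as.data.frame(out)
  names(traj)[1] <- "time"
  # clamp tolerance-level negatives on output only
  traj[-1][traj[-1] < 0] <- 0
  attr(traj, "subject_id") <- subject_id
  attr(traj, "config") <- config
  class(traj) <- c("trajectory", "data.frame")
  traj
}

# Fixed-step classical RK4 integration of the same network (compiled),
# sampling every `sample_every` steps. Used to verify the adaptive solution.
rk4_trajectory <- function(composition, config = sim_config(),
                           means = mean_concentrations(),
                           network = NULL, dt = 1e-3,
                           sample_every = round(1 / dt)) {
  if (is.null(network)) {
    network <- tf_pathway_network(
      include_tf_viia_at = config$include_tf_viia_at)
  }
  y0 <- build_initial_state(composition, means, config)
  nsteps <- round(config$t_end / dt)
  m <- .Call(C_rk4_integrate, as.numeric(y0), encode_network(network),
             as.numeric(dt), as.numeric(nsteps), as.numeric(sample_every))
  colnames(m) <- network$species
  traj <- data.frame(time = seq(0, config$t_end, by = dt * sample_every), m)
  class(traj) <- c("trajectory", "data.frame")
  traj
}

# Direct compiled evaluation of the RHS at one state (test hook).
compiled_derivative <- function(state, network) {
  y <- as.numeric(state[network$species])
  d <- .Call(C_mass_action_rhs, y, encode_network(network))
  setNames(d, network$species)
}

#' Per-grid-point moiety totals of a trajectory
#'
#' @param trajectory A trajectory from [simulate_subject()].
#' @param network The network the trajectory was produced with.
#' @return Matrix (grid points x moieties) of summed molar concentrations.
#' @export
moiety_totals <- function(trajectory, network = tf_pathway_network()) {
  as.matrix(trajectory[, network$species]) %*% network$M
}

#' Write / read a trajectory as tab-separated text
#'
#' Column 1 is time in seconds; remaining columns are species molar
#' concentrations with a header row of species names.
#'
#' @param trajectory A trajectory data frame.
#' @param path Output file path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns the trajectory data frame.
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.table(trajectory, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  traj <- utils::read.delim(path, check.names = FALSE)
  class(traj) <- c("trajectory", "data.frame")
  traj
}
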