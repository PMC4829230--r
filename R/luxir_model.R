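#' Parameters of the heuristic LuxIR/AHL cell model
#'
#' The LuxIR circuit is modeled heuristically: cells synthesize AHL at a
#' baseline rate; once intracellular AHL first exceeds a threshold, synthesis
#' ramps linearly to a maximal rate over a fixed period (capturing system
#' cooperativity and the transcription/translation lag); AHL crosses the
#' membrane by conductance-driven exchange proportional to the
#' concentration difference.
#'
#' @param r_basal_mean mean baseline AHL synthesis rate (uM/min).
#' @param sigma lognormal spread of the baseline rate across cells
#'   (standard deviation of the base-10 logarithm).
#' @param threshold intracellular AHL concentration triggering the ramp
#'   (uM).
#' @param r_max maximal AHL synthesis rate (uM/min).
#' @param ramp time to reach `r_max` after threshold crossing (min).
#' @param conductivity membrane exchange coefficient (1/min) acting on the
#'   intracellular-extracellular concentration difference.
#' @param active_fold synthesis-rate fold over baseline at which a cell is
#'   classified active.
#' @param degradation optional first-order AHL loss rate (1/min); none is
#'   modeled by default.
#' @return an object of class `lux_params`.
#' @export
lux_params <- function(r_basal_mean = 1, sigma = 0.0225, threshold = 2.9,
                       r_max = 10, ramp = 30, conductivity = 0.6,
                       active_fold = 5, degradation = 0) {
  p <- list(r_basal_mean = r_basal_mean, sigma = sigma, threshold = threshold,
            r_max = r_max, ramp = ramp, conductivity = conductivity,
            active_fold = active_fold, degradation = degradation)
  for (nm in names(p))
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) ||
        p[[nm]] < 0)
      stop("lux_params: '", nm, "' must be a single finite non-negative number",
           call. = FALSE)
  if (p$r_max <= p$r_basal_mean)
    stop("lux_params: r_max must exceed r_basal_mean", call. = FALSE)
  if (p$threshold <= 0) stop("lux_params: threshold must be positive",
                             call. = FALSE)
  if (p$conductivity <= 0) stop("lux_params: conductivity must be positive",
                                call. = FALSE)
  class(p) <- "lux_params"
  p
}

#' State of one LuxIR cell
#'
#' @param AHL_in intracellular AHL (uM).
#' @param r_basal this cell's baseline synthesis rate (uM/min).
#' @param t_since_threshold minutes since first threshold crossing, or `NA`
#'   if never crossed. The crossing latches: the ramp never resets even if
#'   intracellular AHL later dips below the threshold.
#' @return an object of class `lux_state`.
#' @export
lux_state <- function(AHL_in = 0, r_basal = 1, t_since_threshold = NA_real_) {
  s <- list(AHL_in = AHL_in, r_basal = r_basal,
            t_since_threshold = t_since_threshold)
  class(s) <- "lux_state"
  s
}

#' Current AHL synthesis rate of a LuxIR cell
#'
#' Baseline before the threshold has been crossed; afterwards a linear ramp
#' from the cell's baseline to `r_max` over the ramp period, then constant.
#'
#' @param state a [lux_state()].
#' @param params a [lux_params()].
#' @return synthesis rate (uM/min).
#' @export
lux_synth_rate <- function(state, params) {
  if (is.na(state$t_since_threshold)) return(state$r_basal)
  frac <- min(state$t_since_threshold / params$ramp, 1)
  state$r_basal + (params$r_max - state$r_basal) * frac
}

#' Advance one LuxIR cell by one time step
#'
#' Synthesis adds `rate * dt` to intracellular AHL; membrane flux
#' `conductivity * (AHL_in - Ae_local) * dt` leaves the cell (entering it
#' when the gradient reverses). The returned exchange is expressed in
#' intracellular-concentration units (uM of cell volume); multiply by the
#' cell/element volume ratio to update the environment. Threshold crossing
#' is checked on the instantaneous post-update concentration and latches.
#'
#' @param state a [lux_state()].
#' @param params a [lux_params()].
#' @param Ae_local extracellular AHL at the cell (uM), non-negative.
#' @param dt time step (min), positive.
#' @return list with `state` (updated) and `exchanged` (uM of cell volume
#'   moved from cell to environment; negative when the cell takes AHL up).
#' @export
lux_step <- function(state, params, Ae_local, dt) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive", call. = FALSE)
  if (Ae_local < 0) stop("Ae_local must be non-negative", call. = FALSE)
  rate <- lux_synth_rate(state, params)
  flux <- params$conductivity * (state$AHL_in - Ae_local)   # uM/min out of cell
  AHL_new <- state$AHL_in + (rate - flux -
                             params$degradation * state$AHL_in) * dt
  if (AHL_new < 0) AHL_new <- 0
  t_new <- state$t_since_threshold
  if (!is.na(t_new)) {
    t_new <- t_new + dt
  } else if (AHL_new > params$threshold) {
    t_new <- 0
  }
  list(state = lux_state(AHL_new, state$r_basal, t_new),
       exchanged = flux * dt)
}

#' Classify a LuxIR cell as active
#'
#' A cell is active when its current AHL synthesis rate is at least
#' `active_fold` times its own baseline rate.
#'
#' @param state a [lux_state()].
#' @param r_basal_cell the cell's baseline synthesis rate (uM/min),
#'   positive.
#' @param params a [lux_params()].
#' @return logical flag.
#' @export
classify_lux <- function(state, r_basal_cell = state$r_basal,
                         params = lux_params()) {
  if (r_basal_cell <= 0) stop("r_basal_cell must be positive", call. = FALSE)
  lux_synth_rate(state, params) >= params$active_fold * r_basal_cell
}
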