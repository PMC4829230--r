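#' Parameters of the Lsr/AI-2 signaling circuit
#'
#' Constructs and validates the rate constants of the single-cell Lsr model.
#' The circuit couples five states: extracellular AI-2 local to the cell
#' (`Ae`, uM), free intracellular AI-2 (`Ai`, uM), phospho-AI-2 (`Ap`, uM),
#' lsr mRNA (`M`, uM-equivalent transcript level) and Lsr transporter protein
#' (`T`, uM). LsrR repression is folded into the Hill transcription term:
#' phospho-AI-2 sequesters the repressor, so transcription is an increasing
#' Hill function of `Ap`.
#'
#' Defaults are calibrated so that a batch culture seeded at an optical
#' density of 0.03 autoinduces shortly after the four-hour mark, with the
#' abrupt mRNA rise, extracellular AI-2 collapse and phospho-AI-2 surge
#' characteristic of Lsr autoinduction.
#'
#' @param K_synth AI-2 synthesis rate (uM/min), the activated-methyl-cycle
#'   source, independent of Lsr activity.
#' @param V_ydgG first-order AI-2 export rate constant through YdgG/TqsA
#'   (1/min).
#' @param basal maximal AI-2 import rate through low-affinity routes
#'   (ribose transporters, PTS) (uM/min). The primary heterogeneity axis.
#' @param K_basal half-saturation of the low-affinity import routes (uM).
#' @param k_phos basal AI-2 phosphorylation rate constant (1/min),
#'   uninduced LsrK level.
#' @param k_pK increment of the phosphorylation rate constant per unit of
#'   Lsr transporter protein (1/min/uM); LsrK is expressed with the operon,
#'   so kinase capacity scales with induction.
#' @param d_Ap phospho-AI-2 turnover rate (1/min), LsrFG-mediated catabolism.
#' @param V_ind induced import rate constant per unit transporter
#'   (1/min/uM).
#' @param K_ind half-saturation of induced LsrACDB import (uM).
#' @param a0 basal (repressed) transcription rate (uM/min).
#' @param a_M maximal additional transcription rate upon de-repression
#'   (uM/min).
#' @param k2 transcription Hill parameter: phospho-AI-2 level at
#'   half-maximal de-repression (uM).
#' @param hill_n Hill coefficient of de-repression (dimensionless). The
#'   default is steep, encoding switch-like cooperative release of LsrR.
#' @param d_M mRNA degradation rate (1/min).
#' @param k_T translation rate constant (1/min).
#' @param d_T transporter protein turnover/dilution rate (1/min).
#' @param activation_fold fold-increase of `T` over its initial reference
#'   at which a cell is classified QS-positive.
#' @param extras named list of additional constants carried verbatim (used
#'   by the SBML round trip).
#' @return an object of class `lsr_params` (a validated named list).
#' @seealso [lsr_rhs()], [integrate_batch()], [two_cell_shared_pool()]
#' @export
lsr_params <- function(K_synth = 60, V_ydgG = 8, basal = 487.8, K_basal = 1,
                       k_phos = 0.2, k_pK = 0.08, d_Ap = 8,
                       V_ind = 10, K_ind = 60,
                       a0 = 0.002, a_M = 10, k2 = 2.8, hill_n = 12,
                       d_M = 0.2, k_T = 0.4, d_T = 0.1,
                       activation_fold = 5, extras = list()) {
  p <- list(K_synth = K_synth, V_ydgG = V_ydgG, basal = basal,
            K_basal = K_basal, k_phos = k_phos, k_pK = k_pK, d_Ap = d_Ap,
            V_ind = V_ind, K_ind = K_ind, a0 = a0, a_M = a_M, k2 = k2,
            hill_n = hill_n, d_M = d_M, k_T = k_T, d_T = d_T,
            activation_fold = activation_fold, extras = extras)
  validate_lsr_params(p)
  class(p) <- "lsr_params"
  p
}

validate_lsr_params <- function(p) {
  rates <- setdiff(names(p), c("extras", "activation_fold"))
  for (nm in rates) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("lsr_params: '", nm, "' must be a single finite non-negative number",
           call. = FALSE)
  }
  if (p$activation_fold <= 1)
    stop("lsr_params: 'activation_fold' must exceed 1", call. = FALSE)
  invisible(p)
}

#' Uninduced steady state of a closed Lsr cell
#'
#' Analytic fixed point of the circuit with no extracellular AI-2: synthesis
#' balances export and basal phosphorylation, and transcription sits at its
#' repressed level. Used as the initial condition of every simulation and as
#' the `T` reference for the fold-activation rule.
#'
#' @param params an [lsr_params()] object.
#' @return named numeric vector `(Ae, Ai, Ap, M, T)`.
#' @export
lsr_initial_state <- function(params = lsr_params()) {
  p <- params
  Ai <- p$K_synth / (p$V_ydgG + p$k_phos)
  Ap <- if (p$k_phos * Ai == 0) 0 else p$k_phos * Ai / p$d_Ap
  hill <- if (p$k2 == 0) 1 else Ap^p$hill_n / (p$k2^p$hill_n + Ap^p$hill_n)
  M <- (p$a0 + p$a_M * hill) / p$d_M
  T0 <- if (p$d_T > 0) p$k_T * M / p$d_T else 0
  c(Ae = 0, Ai = unname(Ai), Ap = unname(Ap), M = unname(M), T = unname(T0))
}

#' Term registry of the Lsr right-hand side
#'
#' Each named influence on the Lsr circuit is one entry: a rate function of
#' `(state, params)` returning a non-negative flux (uM/min, intracellular
#' convention) and a stoichiometry vector over `(Ae, Ai, Ap, M, T)`.
#' Extracellular entries are expressed per intracellular volume and are
#' scaled by `volume_ratio` when the derivative is assembled, so that every
#' AI-2 molecule crossing the membrane is conserved between compartments.
#'
#' @return named list of terms, each `list(rate = function, stoich = vector)`.
#' @seealso [lsr_rhs()]
#' @export
lsr_terms <- function() {
  list(
    synthesis = list(
      rate = function(s, p) p$K_synth,
      stoich = c(Ae = 0, Ai = 1, Ap = 0, M = 0, T = 0)),
    export = list(
      rate = function(s, p) p$V_ydgG * s[["Ai"]],
      stoich = c(Ae = 1, Ai = -1, Ap = 0, M = 0, T = 0)),
    basal_import = list(
      rate = function(s, p) p$basal * s[["Ae"]] / (p$K_basal + s[["Ae"]]),
      stoich = c(Ae = -1, Ai = 1, Ap = 0, M = 0, T = 0)),
    induced_import = list(
      rate = function(s, p) p$V_ind * s[["T"]] * s[["Ae"]] / (p$K_ind + s[["Ae"]]),
      stoich = c(Ae = -1, Ai = 1, Ap = 0, M = 0, T = 0)),
    phosphorylation = list(
      rate = function(s, p) (p$k_phos + p$k_pK * s[["T"]]) * s[["Ai"]],
      stoich = c(Ae = 0, Ai = -1, Ap = 1, M = 0, T = 0)),
    ap_turnover = list(
      rate = function(s, p) p$d_Ap * s[["Ap"]],
      stoich = c(Ae = 0, Ai = 0, Ap = -1, M = 0, T = 0)),
    transcription = list(
      rate = function(s, p) {
        hill <- s[["Ap"]]^p$hill_n / (p$k2^p$hill_n + s[["Ap"]]^p$hill_n)
        p$a0 + p$a_M * hill
      },
      stoich = c(Ae = 0, Ai = 0, Ap = 0, M = 1, T = 0)),
    mrna_decay = list(
      rate = function(s, p) p$d_M * s[["M"]],
      stoich = c(Ae = 0, Ai = 0, Ap = 0, M = -1, T = 0)),
    translation = list(
      rate = function(s, p) p$k_T * s[["M"]],
      stoich = c(Ae = 0, Ai = 0, Ap = 0, M = 0, T = 1)),
    protein_turnover = list(
      rate = function(s, p) p$d_T * s[["T"]],
      stoich = c(Ae = 0, Ai = 0, Ap = 0, M = 0, T = -1))
  )
}

.lsr_state_names <- c("Ae", "Ai", "Ap", "M", "T")

#' Right-hand side of the single-cell Lsr ODE system
#'
#' Assembles the instantaneous time derivative of every state variable from
#' the term registry. Membrane-crossing terms appear in `Ae` scaled by
#' `volume_ratio`, the ratio of cell volume to the extracellular volume the
#' cell exchanges with, so AI-2 moles are conserved across compartments.
#'
#' @param state named numeric vector `(Ae, Ai, Ap, M, T)`, all finite and
#'   non-negative.
#' @param params an [lsr_params()] object.
#' @param volume_ratio cell volume : extracellular volume (dimensionless).
#'   The default pairs a 1 um^3 cell with a 24 um^3 grid element.
#' @return named numeric vector of derivatives (uM/min).
#' @export
lsr_rhs <- function(state, params, volume_ratio = 1 / 24) {
  if (!all(.lsr_state_names %in% names(state)))
    stop("state must contain ", paste(.lsr_state_names, collapse = ", "),
         call. = FALSE)
  state <- state[.lsr_state_names]
  if (any(!is.finite(state)))
    stop("non-finite state variable: ",
         paste(.lsr_state_names[!is.finite(state)], collapse = ", "),
         call. = FALSE)
  if (any(state < 0))
    stop("negative state variable: ",
         paste(.lsr_state_names[state < 0], collapse = ", "), call. = FALSE)
  validate_lsr_params(params)
  d <- c(Ae = 0, Ai = 0, Ap = 0, M = 0, T = 0)
  for (term in lsr_terms()) {
    r <- term$rate(state, params)
    st <- term$stoich
    st["Ae"] <- st["Ae"] * volume_ratio
    d <- d + r * st
  }
  d
}

## deSolve wrapper shared by the batch and multi-cell reference solvers.
## `cells` is a list of lsr_params; one shared Ae couples them; phi(t) is the
## per-cell volume fraction (cell volume over extracellular volume).
.lsr_pool_rhs <- function(t, y, parms) {
  cells <- parms$cells
  n <- length(cells)
  phi <- parms$phi(t) / n
  Ae <- y[1]
  d <- numeric(1 + 4 * n)
  for (k in seq_len(n)) {
    p <- cells[[k]]
    i <- 1 + (k - 1) * 4
    Ai <- y[i + 1]; Ap <- y[i + 2]; M <- y[i + 3]; T <- y[i + 4]
    exp_ <- p$V_ydgG * Ai
    bas <- p$basal * Ae / (p$K_basal + Ae)
    ind <- p$V_ind * T * Ae / (p$K_ind + Ae)
    kp <- p$k_phos + p$k_pK * T
    hill <- Ap^p$hill_n / (p$k2^p$hill_n + Ap^p$hill_n)
    d[1] <- d[1] + phi * (exp_ - bas - ind)
    d[i + 1] <- p$K_synth - exp_ + bas + ind - kp * Ai
    d[i + 2] <- kp * Ai - p$d_Ap * Ap
    d[i + 3] <- p$a0 + p$a_M * hill - p$d_M * M
    d[i + 4] <- p$k_T * M - p$d_T * T
  }
  list(d)
}

#' Exponentially growing batch-culture volume fraction
#'
#' Returns `phi(t)`, the total cell volume fraction of a batch culture
#' growing exponentially from an initial optical-density equivalent. At
#' OD600 0.03 with 8e8 cells/mL/OD and 1 um^3 cells the initial fraction is
#' 2.4e-5.
#'
#' @param od0 initial OD600-equivalent.
#' @param doubling doubling time (min).
#' @param cells_per_ml_od cell concentration per unit OD600 (cells/mL).
#' @param cell_volume cell volume (um^3).
#' @return function of time (min) returning the volume fraction.
#' @export
batch_density <- function(od0 = 0.03, doubling = 40,
                          cells_per_ml_od = 8e8, cell_volume = 1) {
  phi0 <- od0 * cells_per_ml_od * cell_volume * 1e-12
  function(t) phi0 * 2^(t / doubling)
}

#' Integrate the Lsr circuit for a well-mixed batch culture
#'
#' Solves the single representative cell coupled to a shared extracellular
#' pool whose exchange strength follows the (growing) culture density. Uses
#' the stiff implicit backward-differentiation solver as reference
#' (rtol 1e-8, atol 1e-10): autoinduction commitment is abrupt and defeats
#' non-stiff integrators. Integration steps that would drive a state
#' negative are rejected and retried smaller by the solver's own error
#' control; states are never clipped.
#'
#' @param params an [lsr_params()] object.
#' @param cell_density_series function of time (min) returning the culture
#'   volume fraction; defaults to [batch_density()].
#' @param t_end end time (min).
#' @param dt output sampling interval (min).
#' @param state0 optional initial state; defaults to [lsr_initial_state()].
#' @return data.frame with columns `time, Ae, Ai, Ap, M, T`.
#' @export
integrate_batch <- function(params = lsr_params(),
                            cell_density_series = batch_density(),
                            t_end = 420, dt = 1, state0 = NULL) {
  validate_lsr_params(params)
  if (t_end <= 0) stop("t_end must be positive", call. = FALSE)
  y0 <- if (is.null(state0)) lsr_initial_state(params) else state0[.lsr_state_names]
  y <- c(y0[["Ae"]], y0[["Ai"]], y0[["Ap"]], y0[["M"]], y0[["T"]])
  times <- seq(0, t_end, by = dt)
  sol <- deSolve::ode(y, times, .lsr_pool_rhs,
                      list(cells = list(params), phi = cell_density_series),
                      method = "bdf", rtol = 1e-8, atol = 1e-10,
                      maxsteps = 100000)
  if (attr(sol, "istate")[1] < 0)
    stop("integrate_batch: solver failed, istate = ", attr(sol, "istate")[1],
         call. = FALSE)
  bad <- !stats::complete.cases(sol)
  if (any(bad))
    stop("integrate_batch: non-finite state at t = ", sol[which(bad)[1], 1],
         call. = FALSE)
  out <- as.data.frame(sol)
  names(out) <- c("time", .lsr_state_names)
  out
}

#' Two Lsr cells sharing one extracellular AI-2 pool
#'
#' Integrates a pair of Lsr circuits coupled only through a common
#' extracellular pool. With different `basal` values the high-`basal` cell
#' autoinduces first and, by drawing the shared pool down, can permanently
#' prevent the other from activating.
#'
#' @param paramsA,paramsB [lsr_params()] objects for the two cells.
#' @param t_end end time (min).
#' @param dt output sampling interval (min).
#' @param cell_density_series shared-pool volume-fraction series (total for
#'   both cells); defaults to [batch_density()].
#' @return data.frame with `time`, `Ae`, and suffixed per-cell columns
#'   (`Ai_A`, ..., `T_B`).
#' @export
two_cell_shared_pool <- function(paramsA, paramsB, t_end = 420, dt = 1,
                                 cell_density_series = batch_density()) {
  validate_lsr_params(paramsA); validate_lsr_params(paramsB)
  y0A <- lsr_initial_state(paramsA); y0B <- lsr_initial_state(paramsB)
  y <- c(0, y0A[c("Ai", "Ap", "M", "T")], y0B[c("Ai", "Ap", "M", "T")])
  times <- seq(0, t_end, by = dt)
  sol <- deSolve::ode(unname(y), times, .lsr_pool_rhs,
                      list(cells = list(paramsA, paramsB),
                           phi = cell_density_series),
                      method = "bdf", rtol = 1e-8, atol = 1e-10,
                      maxsteps = 100000)
  if (attr(sol, "istate")[1] < 0)
    stop("two_cell_shared_pool: solver failed, istate = ",
         attr(sol, "istate")[1], call. = FALSE)
  out <- as.data.frame(sol)
  names(out) <- c("time", "Ae",
                  paste0(c("Ai", "Ap", "M", "T"), "_A"),
                  paste0(c("Ai", "Ap", "M", "T"), "_B"))
  out
}

#' Smallest `basal` at which the second cell still activates
#'
#' Bisects `basal_B` between `lo` and `basal_A` for the activation boundary
#' of cell B in [two_cell_shared_pool()] by the fold rule on its transporter.
#'
#' @param paramsA parameters of the reference cell.
#' @param lo lower bracket for `basal_B` (uM/min).
#' @param t_end horizon (min).
#' @param tol bisection tolerance (uM/min).
#' @return smallest `basal_B` found to activate by `t_end`.
#' @export
min_activating_basal <- function(paramsA = lsr_params(), lo = 0,
                                 t_end = 420, tol = 1) {
  activates <- function(b) {
    pB <- paramsA; pB$basal <- b
    tr <- two_cell_shared_pool(paramsA, pB, t_end = t_end, dt = 2)
    T0 <- lsr_initial_state(pB)[["T"]]
    any(tr$T_B > paramsA$activation_fold * T0)
  }
  hi <- paramsA$basal
  if (!activates(hi)) return(NA_real_)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (activates(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Write a trajectory to CSV
#'
#' @param trajectory data.frame as returned by [integrate_batch()] or
#'   [two_cell_shared_pool()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.csv(trajectory, path, row.names = FALSE)
  invisible(path)
}
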