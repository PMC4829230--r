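#' Lognormal cell-to-cell heterogeneity specification
#'
#' Describes the distribution from which one model parameter is assigned
#' per cell, as a reflection of natural variability in cellular
#' constituents. Values are drawn once per cell and maintained throughout
#' simulated time.
#'
#' The spread `sigma` is the standard deviation of the logarithm of the
#' parameter; `log_base` states which logarithm. A coefficient of variation
#' of 0.052 at `sigma = 0.0225` corresponds to the base-10 convention
#' (0.0225 * ln 10 = 0.0518); the base-e convention gives CV 0.0225 at the
#' same sigma. Both are supported explicitly so either printed convention
#' can be reproduced.
#'
#' @param target parameter name: one of `basal`, `K_synth`, `V_ydgG`
#'   (Lsr) or `r_basal` (LuxIR).
#' @param sigma standard deviation of the logarithm (non-negative).
#' @param mu mean of the logarithm (in `log_base` units); give exactly one
#'   of `mu` or `median`.
#' @param median median of the distribution (natural units).
#' @param log_base base of the logarithm `sigma` and `mu` refer to:
#'   `"e"` or `"10"`.
#' @return an object of class `heterogeneity_spec`.
#' @export
heterogeneity_spec <- function(target, sigma, mu = NULL, median = NULL,
                               log_base = c("e", "10")) {
  log_base <- match.arg(as.character(log_base), c("e", "10"))
  known <- c("basal", "K_synth", "V_ydgG", "r_basal")
  if (!target %in% known)
    stop("heterogeneity_spec: unknown target '", target, "'; must be one of ",
         paste(known, collapse = ", "), call. = FALSE)
  if (!is.numeric(sigma) || sigma < 0 || !is.finite(sigma))
    stop("heterogeneity_spec: sigma must be finite and >= 0", call. = FALSE)
  if (is.null(mu) == is.null(median))
    stop("heterogeneity_spec: supply exactly one of mu or median",
         call. = FALSE)
  base_val <- if (log_base == "e") exp(1) else 10
  med <- if (is.null(median)) base_val^mu else median
  if (med <= 0) stop("heterogeneity_spec: median must be positive",
                     call. = FALSE)
  s <- list(target = target, sigma = sigma, median = med,
            log_base = log_base)
  class(s) <- "heterogeneity_spec"
  s
}

#' Draw per-cell parameter values
#'
#' Lognormal samples with the spec's median and log-spread. With
#' `sigma = 0` every value equals the median exactly. Reproducible given
#' `seed`; when `seed` is `NULL` the current RNG stream is used (as the
#' simulation engine does with its dedicated heterogeneity stream).
#'
#' @param spec a [heterogeneity_spec()].
#' @param n number of cells (>= 1).
#' @param seed optional integer seed.
#' @return numeric vector of `n` positive values.
#' @export
sample_parameter <- function(spec, n, seed = NULL) {
  if (!inherits(spec, "heterogeneity_spec"))
    stop("spec must be a heterogeneity_spec", call. = FALSE)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (spec$sigma == 0) return(rep(spec$median, n))
  sdlog <- spec$sigma * if (spec$log_base == "10") log(10) else 1
  stats::rlnorm(n, meanlog = log(spec$median), sdlog = sdlog)
}

#' Population growth specification
#'
#' The population-wide Monod growth rate is taken as a supplied constant and
#' converted into per-cell doubling times, normally distributed from cell to
#' cell with a relative spread.
#'
#' @param growth_rate specific growth rate (1/min); the default corresponds
#'   to a 40-minute mean doubling time.
#' @param cv_doubling coefficient of variation of the per-cell doubling
#'   time.
#' @param floor smallest admissible doubling time (min); draws are
#'   truncated here.
#' @return an object of class `growth_spec`.
#' @export
growth_spec <- function(growth_rate = log(2) / 40, cv_doubling = 0.05,
                        floor = 1) {
  if (growth_rate <= 0) stop("growth_spec: growth_rate must be positive",
                             call. = FALSE)
  if (cv_doubling < 0) stop("growth_spec: cv_doubling must be >= 0",
                            call. = FALSE)
  s <- list(growth_rate = growth_rate, cv_doubling = cv_doubling,
            floor = floor)
  class(s) <- "growth_spec"
  s
}

#' Draw per-cell doubling times
#'
#' Normal around `ln 2 / growth_rate` with relative spread `cv_doubling`,
#' truncated at the spec floor.
#'
#' @param spec a [growth_spec()].
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return numeric vector of doubling times (min), all positive.
#' @export
assign_doubling_time <- function(spec, n = 1, seed = NULL) {
  if (!inherits(spec, "growth_spec")) stop("spec must be a growth_spec",
                                           call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  m <- log(2) / spec$growth_rate
  if (spec$cv_doubling == 0) return(rep(m, n))
  pmax(stats::rnorm(n, m, spec$cv_doubling * m), spec$floor)
}

#' Construct a cell agent
#'
#' A cell agent carries its continuous position, its individually assigned
#' parameter value, its signaling state, the transporter reference for the
#' fold-activation rule, and its division countdown.
#'
#' @param id integer cell id.
#' @param x,y position (um).
#' @param param_value this cell's value of the varied parameter.
#' @param model_state named state vector (Lsr) or [lux_state()] (LuxIR).
#' @param T0_ref transporter reference concentration for the fold rule
#'   (Lsr only).
#' @param doubling_time assigned doubling time (min).
#' @param division_counter minutes remaining until division.
#' @param qs_active logical QS flag.
#' @return an object of class `cell_agent` (a list).
#' @export
cell_agent <- function(id, x, y, param_value, model_state, T0_ref = NA_real_,
                       doubling_time = 40, division_counter = doubling_time,
                       qs_active = FALSE) {
  if (doubling_time <= 0) stop("doubling_time must be positive", call. = FALSE)
  structure(list(id = id, x = x, y = y, param_value = param_value,
                 model_state = model_state, T0_ref = T0_ref,
                 doubling_time = doubling_time,
                 division_counter = division_counter,
                 qs_active = qs_active),
            class = "cell_agent")
}

#' Divide a cell agent
#'
#' The daughter copies the parent's model state, QS flag and transporter
#' reference. Exceptions, as for real division bookkeeping: the varied
#' parameter is redrawn from the heterogeneity distribution (unless
#' `inherit` is set), the doubling time is redrawn, and the position is
#' assigned by the engine's placement rule (the daughter is returned at the
#' parent's position as a placeholder). The parent's counter resets to its
#' own doubling time.
#'
#' @param parent a [cell_agent()] whose `division_counter` has elapsed.
#' @param het a [heterogeneity_spec()] or `NULL` (no varied parameter).
#' @param growth a [growth_spec()].
#' @param new_id id for the daughter.
#' @param inherit if `TRUE` the daughter inherits the parent's varied
#'   parameter instead of redrawing (sensitivity studies only).
#' @return list with `parent` (counter reset) and `daughter`.
#' @export
divide <- function(parent, het, growth, new_id, inherit = FALSE) {
  if (parent$division_counter > 1e-9)
    stop("divide: parent's division counter has not elapsed", call. = FALSE)
  pv <- if (is.null(het) || inherit) parent$param_value
        else sample_parameter(het, 1)
  daughter <- cell_agent(id = new_id, x = parent$x, y = parent$y,
                         param_value = pv,
                         model_state = parent$model_state,
                         T0_ref = parent$T0_ref,
                         doubling_time = assign_doubling_time(growth, 1),
                         qs_active = parent$qs_active)
  parent$division_counter <- parent$doubling_time
  list(parent = parent, daughter = daughter)
}

#' Classify an Lsr cell as QS-positive
#'
#' Active when the Lsr transporter protein concentration exceeds
#' `activation_fold` times the cell's stored initial concentration.
#' Classification is for downstream analysis only and feeds nothing back
#' into the dynamics.
#'
#' @param T_now current transporter concentration (uM).
#' @param T0_ref initial reference concentration (uM), positive.
#' @param activation_fold fold threshold (default 5).
#' @return logical flag.
#' @export
classify_lsr <- function(T_now, T0_ref, activation_fold = 5) {
  if (any(T0_ref <= 0)) stop("classify_lsr: T0_ref must be positive",
                             call. = FALSE)
  T_now > activation_fold * T0_ref
}
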