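#' Geometry and timing of the 2D finite-difference environment
#'
#' A square domain of edge `L` (um) discretized into square elements of edge
#' `dx` with an implied depth, so each element is a small well-mixed volume
#' (24 um^3 at the 2 um / 6 um defaults). The master engine step `dt_engine`
#' is given in seconds. The diffusion coefficient defaults to the
#' Wilke-Chang estimate for DPD (the AI-2 precursor) in water at 310 K.
#'
#' @param L domain edge (um).
#' @param dx element edge (um); must divide `L`.
#' @param depth implied thickness (um).
#' @param dt_engine master time step (s).
#' @param D autoinducer diffusion coefficient (um^2/s).
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(L = 500, dx = 2, depth = 6, dt_engine = 0.0667,
                      D = wilke_chang_D()) {
  n <- L / dx
  if (abs(n - round(n)) > 1e-9)
    stop("grid_spec: L must be an integer multiple of dx", call. = FALSE)
  if (D <= 0) stop("grid_spec: D must be positive", call. = FALSE)
  if (dt_engine <= 0) stop("grid_spec: dt_engine must be positive",
                           call. = FALSE)
  g <- list(L = L, dx = dx, depth = depth, dt_engine = dt_engine, D = D,
            n = as.integer(round(n)), element_volume = dx^2 * depth)
  class(g) <- "grid_spec"
  g
}

#' Wilke-Chang diffusion coefficient estimate
#'
#' `D = 7.4e-8 * sqrt(phi * M) * T / (eta * V^0.6)` in cm^2/s, converted to
#' um^2/s. Defaults estimate DPD (4,5-dihydroxy-2,3-pentanedione, the AI-2
#' precursor; Le Bas additive molar volume 133.2 cm^3/mol) in water at
#' 310 K.
#'
#' @param molar_volume solute molar volume at the normal boiling point
#'   (cm^3/mol).
#' @param temperature absolute temperature (K).
#' @param solvent_viscosity solvent viscosity (cP).
#' @param association_factor solvent association factor (2.6 for water).
#' @param solvent_mw solvent molecular weight (g/mol).
#' @return diffusion coefficient (um^2/s).
#' @export
wilke_chang_D <- function(molar_volume = 133.2, temperature = 310,
                          solvent_viscosity = 0.69, association_factor = 2.6,
                          solvent_mw = 18.015) {
  args <- c(molar_volume = molar_volume, temperature = temperature,
            solvent_viscosity = solvent_viscosity,
            association_factor = association_factor, solvent_mw = solvent_mw)
  bad <- names(args)[!is.finite(args) | args <= 0]
  if (length(bad))
    stop("wilke_chang_D: non-positive input: ", paste(bad, collapse = ", "),
         call. = FALSE)
  D_cm2 <- 7.4e-8 * sqrt(association_factor * solvent_mw) * temperature /
    (solvent_viscosity * molar_volume^0.6)
  D_cm2 * 1e8   # cm^2/s -> um^2/s
}

#' Create a concentration field
#'
#' @param grid a [grid_spec()].
#' @param value initial uniform concentration (uM), or an `n x n` matrix.
#' @return matrix of per-element concentrations (uM), class
#'   `concentration_field`; element `[i, j]` spans
#'   `[(i-1) dx, i dx) x [(j-1) dx, j dx)` um (half-open, origin at (0,0)).
#' @export
concentration_field <- function(grid, value = 0) {
  f <- if (is.matrix(value)) value else matrix(value, grid$n, grid$n)
  if (any(f < 0)) stop("concentration_field: negative concentration",
                       call. = FALSE)
  structure(f, class = c("concentration_field", "matrix", "array"))
}

#' Element index of a position
#'
#' @param grid a [grid_spec()].
#' @param x,y coordinates (um), inside the domain.
#' @return integer matrix with columns `i, j` (1-based row/column index).
#' @export
element_of <- function(grid, x, y) {
  i <- pmin(pmax(floor(x / grid$dx), 0), grid$n - 1) + 1L
  j <- pmin(pmax(floor(y / grid$dx), 0), grid$n - 1) + 1L
  cbind(i = as.integer(i), j = as.integer(j))
}

#' Diffuse the field over one engine step
#'
#' Explicit forward-time centered-space update with no-flux (mirror)
#' boundaries. The requested step is internally divided into sub-steps so
#' the stability number `lambda = D dt_sub / dx^2` never exceeds
#' `lambda_max`; the scheme is then conservative to rounding and respects
#' the discrete maximum principle.
#'
#' @param field a [concentration_field()] (or plain matrix).
#' @param grid a [grid_spec()].
#' @param dt time to advance (s).
#' @param lambda_max cap on the sub-step stability number `D dt_sub / dx^2`.
#'   Values up to 0.25 are stable in 2D, but at exactly 0.25 the center
#'   weight `1 - 4 lambda` vanishes and a checkerboard mode is left
#'   undamped; the default 0.2 keeps all stencil weights positive so the
#'   discrete solution is monotone.
#' @return the diffused field (same class as input).
#' @export
diffuse <- function(field, grid, dt = grid$dt_engine, lambda_max = 0.2) {
  if (dt < 0) stop("diffuse: dt must be non-negative", call. = FALSE)
  if (lambda_max <= 0 || lambda_max > 0.25)
    stop("diffuse: lambda_max must lie in (0, 0.25]", call. = FALSE)
  if (dt == 0) return(field)
  lam_full <- grid$D * dt / grid$dx^2
  n_sub <- max(1L, as.integer(ceiling(lam_full / lambda_max)))
  lam <- lam_full / n_sub
  out <- ftcs_diffuse_cpp(unclass(field), lam, n_sub)
  class(out) <- class(field)
  out
}

#' Exchange moles between a cell and its grid element
#'
#' Applies a net transfer of autoinducer to one element. Withdrawals larger
#' than the element's content are capped at what is present: the element
#' goes exactly to zero and the shortfall is reported back so the cell
#' update can account for supply-limited import.
#'
#' @param field a [concentration_field()].
#' @param grid a [grid_spec()].
#' @param i,j element index (1-based).
#' @param net_umol_um3 amount to add, as concentration-volume
#'   (uM * um^3); negative values withdraw.
#' @return list with `field` (updated) and `shortfall` (uM * um^3 the cell
#'   requested but could not receive; zero unless capped).
#' @export
exchange <- function(field, grid, i, j, net_umol_um3) {
  if (i < 1 || i > grid$n || j < 1 || j > grid$n)
    stop("exchange: element index out of range", call. = FALSE)
  dC <- net_umol_um3 / grid$element_volume
  newC <- field[i, j] + dC
  shortfall <- 0
  if (newC < 0) {
    shortfall <- -newC * grid$element_volume
    newC <- 0
  }
  field[i, j] <- newC
  list(field = field, shortfall = shortfall)
}

#' Total autoinducer in the field
#'
#' @param field a [concentration_field()].
#' @param grid a [grid_spec()].
#' @return total amount (uM * um^3).
#' @export
field_total <- function(field, grid) {
  sum(field) * grid$element_volume
}
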