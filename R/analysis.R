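## Post-processing statistics: activation timing, fractional activation,
## spatial metrics, first-activator statistics.

#' Detect the activation time of a trajectory
#'
#' Fits a first-order linear regression `g(t)` to the trace over a baseline
#' window and returns the earliest sample time at which
#' `f(t) - g(t) > 2 g(t)`, i.e. the trace exceeds three times its
#' extrapolated baseline. Returns `NA` if the criterion is never met.
#'
#' @param time sample times (min), covering at least the fit window.
#' @param f trace values (e.g. phospho-AI-2 or mean AHL synthesis rate).
#' @param window baseline fit window (min), default 12 to 152.
#' @return activation time (min) or `NA`.
#' @export
activation_time <- function(time, f, window = c(12, 152)) {
  if (length(time) != length(f)) stop("time and f lengths differ",
                                      call. = FALSE)
  w <- time >= window[1] & time <= window[2]
  if (sum(w) < 2)
    stop("activation_time: fewer than 2 samples in the fit window",
         call. = FALSE)
  co <- stats::coef(stats::lm(f[w] ~ time[w]))
  g <- co[1] + co[2] * time
  idx <- which(f - g > 2 * g)
  if (length(idx) == 0) return(NA_real_)
  time[min(idx)]
}

#' Activated fraction over time
#'
#' @param record a `run_record`, or a list of replicate records for
#'   mean/sd aggregation.
#' @return data.frame `time, frac` for one record; for replicates, columns
#'   `time, mean, sd` plus one column per replicate.
#' @export
fraction_activated <- function(record) {
  if (inherits(record, "run_record")) {
    if (nrow(record$series) == 0 || record$series$n_cells[1] == 0)
      stop("fraction_activated: empty population", call. = FALSE)
    return(data.frame(time = record$series$time,
                      frac = record$series$frac_active))
  }
  stopifnot(is.list(record), length(record) >= 1)
  fr <- lapply(record, function(r) fraction_activated(r)$frac)
  len <- min(lengths(fr))
  m <- sapply(fr, function(v) v[seq_len(len)])
  tt <- fraction_activated(record[[1]])$time[seq_len(len)]
  out <- data.frame(time = tt, mean = rowMeans(m),
                    sd = apply(m, 1, stats::sd))
  cbind(out, as.data.frame(m))
}

#' Median nearest-neighbor distance
#'
#' Median over cells of each cell's Euclidean distance to its nearest
#' neighbor.
#'
#' @param x,y positions (um), at least two cells.
#' @return distance (um).
#' @export
median_nn_distance <- function(x, y) {
  n <- length(x)
  if (n < 2) stop("median_nn_distance: need at least 2 positions",
                  call. = FALSE)
  d <- as.matrix(stats::dist(cbind(x, y)))
  diag(d) <- Inf
  stats::median(apply(d, 1, min))
}

#' Extracellular autoinducer per induced cell
#'
#' Total extracellular autoinducer in the field divided by the number of
#' induced cells at each recorded time; `NA` (undefined) while no cell is
#' induced. Concentration units: total field amount (uM um^3) divided by
#' the domain volume gives the mean concentration, which is then divided by
#' the induced count.
#'
#' @param record a `run_record`.
#' @return data.frame `time, n_induced, ae_per_cell`.
#' @export
ae_per_induced_cell <- function(record) {
  s <- record$series
  vol <- record$config$grid$L^2 * record$config$grid$depth
  mean_conc <- s$ae_total / vol
  data.frame(time = s$time, n_induced = s$n_active,
             ae_per_cell = ifelse(s$n_active > 0,
                                  mean_conc / s$n_active, NA_real_))
}

#' Colony-center versus induction-center boundary bias
#'
#' For each record, the centers of mass of all cells and of activated cells
#' at the first-activation time. Across replicates, both x and y
#' coordinates are pooled into one least-squares regression of induction
#' center on colony center; a slope above one indicates that induction
#' centers sit farther from the domain center (closer to the boundary)
#' than colony centers.
#'
#' @param records list of `run_record`s (colony mode) with at least one
#'   activation each.
#' @return list with `centers` (data.frame per replicate: colony_x/y,
#'   induction_x/y), `fit` (lm of pooled coordinates, centered on the
#'   domain midpoint) and `slope`.
#' @export
induction_center_bias <- function(records) {
  if (inherits(records, "run_record")) records <- list(records)
  rows <- lapply(records, function(r) {
    fa <- r$first_activation
    if (is.null(fa)) stop("induction_center_bias: record has no activation",
                          call. = FALSE)
    act <- fa[fa$active, ]
    data.frame(colony_x = mean(fa$x), colony_y = mean(fa$y),
               induction_x = mean(act$x), induction_y = mean(act$y))
  })
  cen <- do.call(rbind, rows)
  L <- records[[1]]$config$grid$L
  cc <- c(cen$colony_x, cen$colony_y) - L / 2
  ic <- c(cen$induction_x, cen$induction_y) - L / 2
  fit <- stats::lm(ic ~ cc)
  list(centers = cen, fit = fit, slope = unname(stats::coef(fit)[2]))
}

#' First-activator parameter statistics
#'
#' Per replicate, the varied-parameter value of the earliest activated
#' cell; aggregated as mean and standard deviation, with the pooled
#' population assignment histogram for overlay.
#'
#' @param records list of `run_record`s.
#' @param breaks histogram breaks passed to [graphics::hist()] semantics
#'   (computed with [base::pretty()] over pooled assignments).
#' @return list with `first_values`, `mean`, `sd`, `population`
#'   (pooled assigned values) and `histogram` (data.frame mid/count).
#' @export
first_activator_stats <- function(records, breaks = 30) {
  if (inherits(records, "run_record")) records <- list(records)
  fv <- vapply(records, function(r) {
    ev <- r$events
    if (nrow(ev) == 0) return(NA_real_)
    ev$param_value[which.min(ev$time)]
  }, numeric(1))
  if (all(is.na(fv)))
    stop("first_activator_stats: no record has an activation event",
         call. = FALSE)
  pop <- unlist(lapply(records, function(r) r$assignments$value))
  h <- graphics::hist(pop, breaks = breaks, plot = FALSE)
  list(first_values = fv,
       mean = mean(fv, na.rm = TRUE),
       sd = stats::sd(fv, na.rm = TRUE),
       population = pop,
       histogram = data.frame(mid = h$mids, count = h$counts))
}

#' Local heterogeneity of QS activation
#'
#' Fraction of cell pairs within `radius` whose QS states differ,
#' normalized by `2 p (1 - p)` where `p` is the activated fraction, so a
#' spatially random assignment of states at the same activated fraction
#' scores approximately 1. Scores below 1 indicate spatial clustering of
#' like states (contiguous fronts); above 1, interleaving of unlike states
#' (dispersed, speckled activation). The score is invariant to relabeling
#' active and inactive. This discordant-pair definition is this package's
#' choice of measure.
#'
#' @param x,y positions (um).
#' @param active logical QS flags.
#' @param radius neighborhood radius (um), default 10.
#' @return the score (NA when no pairs lie within the radius or when
#'   `p` is 0 or 1).
#' @export
local_heterogeneity <- function(x, y, active, radius = 10) {
  n <- length(x)
  p <- mean(active)
  if (p <= 0 || p >= 1) return(0)   # uniform state: no discordant pairs
  if (n < 2) return(NA_real_)
  d <- as.matrix(stats::dist(cbind(x, y)))
  within <- d <= radius & upper.tri(d)
  if (!any(within)) return(NA_real_)
  a <- matrix(active, n, n)
  discord <- a != t(a)
  mean(discord[within]) / (2 * p * (1 - p))
}

#' Local-heterogeneity time series of a record
#'
#' Applies [local_heterogeneity()] to every stored snapshot.
#'
#' @param record a `run_record`.
#' @param radius neighborhood radius (um).
#' @return data.frame `time, frac_active, score`.
#' @export
local_heterogeneity_series <- function(record, radius = 10) {
  rows <- lapply(record$snapshots, function(sn) {
    data.frame(time = sn$time[1], frac_active = mean(sn$active),
               score = local_heterogeneity(sn$x, sn$y, sn$active, radius))
  })
  do.call(rbind, rows)
}

#' Plot a colony snapshot
#'
#' QS-active cells red, inactive yellow, on the simulated domain.
#'
#' @param record a `run_record`.
#' @param time snapshot time (min); the nearest stored snapshot is used.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the snapshot plotted.
#' @export
plot_colony <- function(record, time = NULL, ...) {
  tts <- as.numeric(names(record$snapshots))
  k <- if (is.null(time)) length(tts) else which.min(abs(tts - time))
  sn <- record$snapshots[[k]]
  L <- record$config$grid$L
  graphics::plot(sn$x, sn$y, col = ifelse(sn$active, "red", "gold"),
                 pch = 19, cex = 0.5, xlim = c(0, L), ylim = c(0, L),
                 xlab = "x (um)", ylab = "y (um)",
                 main = paste0("t = ", tts[k], " min"), asp = 1, ...)
  invisible(sn)
}

#' Export a summary time series as CSV
#'
#' @param record a `run_record`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_series <- function(record, path) {
  utils::write.csv(record$series, path, row.names = FALSE)
  invisible(path)
}
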