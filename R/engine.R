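## Engine: time stepping, motility, division placement, field coupling.

#' Full simulation configuration
#'
#' @param model `"lsr"` or `"luxir"`.
#' @param motility `"swim"` (run-and-reorient random motility) or `"colony"`
#'   (movement arises only from growth and division pushing).
#' @param grid a [grid_spec()].
#' @param het a [heterogeneity_spec()] or `NULL` for a uniform population.
#' @param growth a [growth_spec()].
#' @param params an [lsr_params()] or [lux_params()] matching `model`.
#' @param t_end simulated time (min).
#' @param initial_density OD600-equivalent of the inoculum.
#' @param od_to_cells_per_ml conversion factor (cells/mL per OD600).
#' @param n_init optional explicit initial cell count, overriding the
#'   density conversion (used for reduced-scale studies).
#' @param seed master seed; four independent sub-streams (placement,
#'   motility, heterogeneity, division) are derived from it.
#' @param record_every cadence of the summary time series (min).
#' @param snapshot_every cadence of full population/field snapshots (min).
#' @param swim_speed mean swimming speed (um/s).
#' @param swim_cv relative spread of the per-step speed draw.
#' @param density_cap maximum cells per grid element in swim mode.
#' @param cell_volume cell volume (um^3).
#' @param inherit_param if `TRUE`, daughters inherit the varied parameter
#'   instead of redrawing it.
#' @param ae_init initial uniform extracellular autoinducer concentration
#'   (uM).
#' @param stop_at_first_activation end the run at the step of the first
#'   activation event (used for first-activator and center-bias replicate
#'   studies).
#' @return an object of class `run_config`.
#' @export
run_config <- function(model = c("lsr", "luxir"),
                       motility = c("swim", "colony"),
                       grid = grid_spec(),
                       het = NULL,
                       growth = growth_spec(),
                       params = NULL,
                       t_end = 400,
                       initial_density = 0.03,
                       od_to_cells_per_ml = 8e8,
                       n_init = NULL,
                       seed = 1,
                       record_every = 1,
                       snapshot_every = 10,
                       swim_speed = 20,
                       swim_cv = 0.05,
                       density_cap = 3,
                       cell_volume = 1,
                       inherit_param = FALSE,
                       ae_init = 0,
                       stop_at_first_activation = FALSE) {
  model <- match.arg(model)
  motility <- match.arg(motility)
  if (is.null(params))
    params <- if (model == "lsr") lsr_params() else lux_params()
  if (model == "lsr" && !inherits(params, "lsr_params"))
    stop("run_config: model 'lsr' requires lsr_params", call. = FALSE)
  if (model == "luxir" && !inherits(params, "lux_params"))
    stop("run_config: model 'luxir' requires lux_params", call. = FALSE)
  if (!inherits(grid, "grid_spec")) stop("run_config: invalid grid",
                                         call. = FALSE)
  if (!is.null(het) && !inherits(het, "heterogeneity_spec"))
    stop("run_config: invalid het", call. = FALSE)
  if (!inherits(growth, "growth_spec")) stop("run_config: invalid growth",
                                             call. = FALSE)
  if (t_end <= 0) stop("run_config: t_end must be positive", call. = FALSE)
  if (!is.null(het)) {
    lsr_targets <- c("basal", "K_synth", "V_ydgG")
    if (model == "lsr" && !het$target %in% lsr_targets)
      stop("run_config: heterogeneity target '", het$target,
           "' does not apply to the lsr model", call. = FALSE)
    if (model == "luxir" && het$target != "r_basal")
      stop("run_config: heterogeneity target '", het$target,
           "' does not apply to the luxir model", call. = FALSE)
  }
  cfg <- list(model = model, motility = motility, grid = grid, het = het,
              growth = growth, params = params, t_end = t_end,
              initial_density = initial_density,
              od_to_cells_per_ml = od_to_cells_per_ml, n_init = n_init,
              seed = as.integer(seed),
              seeds = list(placement = as.integer(seed) + 101L,
                           motility = as.integer(seed) + 202L,
                           heterogeneity = as.integer(seed) + 303L,
                           division = as.integer(seed) + 404L),
              record_every = record_every, snapshot_every = snapshot_every,
              swim_speed = swim_speed, swim_cv = swim_cv,
              density_cap = density_cap, cell_volume = cell_volume,
              inherit_param = inherit_param, ae_init = ae_init,
              stop_at_first_activation = stop_at_first_activation)
  class(cfg) <- "run_config"
  cfg
}

## ---- independent RNG streams -------------------------------------------

make_streams <- function(seeds) {
  e <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  for (nm in names(seeds)) {
    set.seed(seeds[[nm]])
    assign(nm, get(".Random.seed", globalenv()), envir = e)
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  e
}

with_stream <- function(streams, name, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", get(name, envir = streams), envir = globalenv())
  res <- expr
  assign(name, get(".Random.seed", globalenv()), envir = streams)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  res
}

## ---- motility -----------------------------------------------------------

#' Mirror-reflect positions into the domain
#'
#' A projected position `d` beyond a boundary is relocated `d` inside it
#' (twice the distance from the projected point). Applied per axis, so
#' corner overshoots reflect independently in x and y.
#'
#' @param x numeric positions (um).
#' @param L domain edge (um).
#' @return reflected positions within `[0, L]`.
#' @export
reflect_position <- function(x, L) {
  for (k in 1:100) {
    out <- x < 0 | x > L
    if (!any(out)) break
    x <- ifelse(x < 0, -x, x)
    x <- ifelse(x > L, 2 * L - x, x)
  }
  x
}

#' One swim update for a set of cells
#'
#' Step lengths are `speed * dt` with per-step speeds drawn from a normal
#' distribution (mean `swim_speed`, cv `swim_cv`); directions are uniform.
#' Projected positions beyond the boundary are mirror-reflected; moves into
#' an element already holding `density_cap` cells are rejected and the cell
#' stays put (cells are processed in index order).
#'
#' @param x,y current positions (um).
#' @param counts integer occupancy matrix (cells per element).
#' @param grid a [grid_spec()].
#' @param dt time step (s).
#' @param speed mean speed (um/s).
#' @param cv relative speed spread.
#' @param cap density cap per element.
#' @return list with updated `x`, `y`, `counts`, and the drawn `step`
#'   lengths (um).
#' @export
move_swim <- function(x, y, counts, grid, dt, speed = 20, cv = 0.05,
                      cap = 3) {
  if (dt <= 0) stop("move_swim: dt must be positive", call. = FALSE)
  n <- length(x)
  step <- stats::rnorm(n, speed * dt, cv * speed * dt)
  step[step < 0] <- 0
  theta <- stats::runif(n, 0, 2 * pi)
  px <- reflect_position(x + step * cos(theta), grid$L)
  py <- reflect_position(y + step * sin(theta), grid$L)
  mv <- apply_moves_cpp(x, y, px, py, counts, grid$dx, cap)
  list(x = mv$x, y = mv$y, counts = mv$counts, step = step)
}

## ---- colony placement ---------------------------------------------------

## 8-neighborhood offsets
.nbr <- cbind(i = c(-1, -1, -1, 0, 0, 1, 1, 1),
              j = c(-1, 0, 1, -1, 1, -1, 0, 1))

#' Place a daughter cell in a growing colony
#'
#' Boundary parents (with a free adjacent element) place the daughter
#' uniformly at random among free adjacent elements. Interior parents push
#' a chain of cells one element each along the shortest path through the
#' colony to unoccupied space (ties broken uniformly at random); the
#' daughter takes the vacated slot next to the parent.
#'
#' @param parent_elem parent element index `c(i, j)` (1-based).
#' @param occ integer occupancy matrix (0/1 in colony mode).
#' @param grid a [grid_spec()].
#' @return list with `daughter` element index, updated `occ`, and `moves`
#'   (matrix of chain relocations `from_i, from_j, to_i, to_j`, possibly
#'   empty).
#' @export
colony_placement <- function(parent_elem, occ, grid) {
  n <- grid$n
  pi_ <- parent_elem[1]; pj <- parent_elem[2]
  if (occ[pi_, pj] <= 0) stop("colony_placement: parent element empty",
                              call. = FALSE)
  free_adj <- function(i, j) {
    ii <- i + .nbr[, 1]; jj <- j + .nbr[, 2]
    ok <- ii >= 1 & ii <= n & jj >= 1 & jj <= n
    ii <- ii[ok]; jj <- jj[ok]
    free <- occ[cbind(ii, jj)] == 0
    cbind(ii[free], jj[free])
  }
  fa <- free_adj(pi_, pj)
  if (nrow(fa) > 0) {
    k <- if (nrow(fa) == 1) 1L else sample.int(nrow(fa), 1)
    d <- fa[k, ]
    occ[d[1], d[2]] <- 1L
    return(list(daughter = d, occ = occ,
                moves = matrix(numeric(0), 0, 4)))
  }
  ## interior: BFS through occupied elements to the nearest free element
  prev <- matrix(NA_integer_, n * n, 1)
  dist <- matrix(-1L, n, n)
  dist[pi_, pj] <- 0L
  queue <- matrix(c(pi_, pj), 1, 2)
  target <- NULL
  while (nrow(queue) > 0 && is.null(target)) {
    ## expand the whole frontier, collecting any free elements reached
    nxt <- NULL
    hits <- NULL
    for (q in seq_len(nrow(queue))) {
      ci <- queue[q, 1]; cj <- queue[q, 2]
      ord <- sample.int(8)        # uniform tie-break from the caller stream
      for (k in ord) {
        ii <- ci + .nbr[k, 1]; jj <- cj + .nbr[k, 2]
        if (ii < 1 || ii > n || jj < 1 || jj > n) next
        if (dist[ii, jj] >= 0) next
        dist[ii, jj] <- dist[ci, cj] + 1L
        prev[(jj - 1) * n + ii] <- (cj - 1) * n + ci
        if (occ[ii, jj] == 0) hits <- rbind(hits, c(ii, jj))
        else nxt <- rbind(nxt, c(ii, jj))
      }
    }
    if (!is.null(hits)) {
      k <- if (nrow(hits) == 1) 1L else sample.int(nrow(hits), 1)
      target <- hits[k, ]
    }
    queue <- if (is.null(nxt)) matrix(numeric(0), 0, 2) else nxt
  }
  if (is.null(target))
    stop("colony_placement: no reachable free element (domain full)",
         call. = FALSE)
  ## reconstruct path parent -> target
  path <- list()
  cur <- (target[2] - 1) * n + target[1]
  repeat {
    path[[length(path) + 1]] <- c((cur - 1) %% n + 1, (cur - 1) %/% n + 1)
    if (cur == (pj - 1) * n + pi_) break
    cur <- prev[cur]
  }
  path <- do.call(rbind, rev(path))   # row 1 = parent, last = free target
  ## shift each occupant one step outward along the path
  moves <- NULL
  for (k in rev(seq_len(nrow(path) - 1))) {
    if (k == 1) break
    moves <- rbind(moves, c(path[k, ], path[k + 1, ]))
  }
  for (m in seq_len(nrow(moves))) {
    occ[moves[m, 3], moves[m, 4]] <- 1L
    occ[moves[m, 1], moves[m, 2]] <- 0L
  }
  d <- path[2, ]
  occ[d[1], d[2]] <- 1L
  list(daughter = d, occ = occ,
       moves = if (is.null(moves)) matrix(numeric(0), 0, 4) else moves)
}

## ---- initialization helpers --------------------------------------------

initial_cell_count <- function(cfg) {
  if (!is.null(cfg$n_init)) return(as.integer(cfg$n_init))
  vol_ml <- cfg$grid$L^2 * cfg$grid$depth * 1e-12
  max(1L, as.integer(round(cfg$initial_density * cfg$od_to_cells_per_ml *
                             vol_ml)))
}

## Lsr parameter matrix column order must match the C++ enum.
.lsr_par_cols <- c("K_synth", "V_ydgG", "basal", "K_basal", "k_phos", "k_pK",
                   "d_Ap", "V_ind", "K_ind", "a0", "a_M", "k2", "hill_n",
                   "d_M", "k_T", "d_T")

lsr_par_matrix <- function(params, n) {
  m <- matrix(rep(unlist(params[.lsr_par_cols]), each = n), nrow = n)
  colnames(m) <- .lsr_par_cols
  m
}

## Vectorized uninduced steady state for per-cell parameter rows.
lsr_initial_rows <- function(pm) {
  Ai <- pm[, "K_synth"] / (pm[, "V_ydgG"] + pm[, "k_phos"])
  flux <- pm[, "k_phos"] * Ai
  Ap <- ifelse(flux == 0, 0, flux / pm[, "d_Ap"])
  hill <- Ap^pm[, "hill_n"] /
    (pm[, "k2"]^pm[, "hill_n"] + Ap^pm[, "hill_n"])
  M <- (pm[, "a0"] + pm[, "a_M"] * hill) / pm[, "d_M"]
  T0 <- ifelse(pm[, "d_T"] > 0, pm[, "k_T"] * M / pm[, "d_T"], 0)
  cbind(Ai = Ai, Ap = Ap, M = M, T = T0)
}

## ---- the simulation loop ------------------------------------------------

#' Run an agent-based quorum-sensing simulation
#'
#' Advances the configured population and extracellular field through fixed
#' engine steps. Per step, in order: motility (swim mode), per-cell model
#' integration coupled to the local grid element (exchange included),
#' diffusion sub-steps, division checks, classification and recording.
#' Identical configurations and seeds reproduce the record exactly.
#'
#' @param cfg a [run_config()].
#' @return an object of class `run_record`: list with `config`, `series`
#'   (per-cadence summary data.frame), `snapshots` (list of population
#'   tables), `field_snapshots`, `events` (activation events),
#'   `assignments` (per-cell varied-parameter values),
#'   `first_activation` (population table at the first activation step,
#'   or `NULL`), and `T0_ref`.
#' @export
run_simulation <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  grid <- cfg$grid
  streams <- make_streams(cfg$seeds)
  dt_min <- grid$dt_engine / 60
  n_steps <- as.integer(round(cfg$t_end / dt_min))
  rec_steps <- max(1L, as.integer(round(cfg$record_every / dt_min)))
  snap_steps <- max(1L, as.integer(round(cfg$snapshot_every / dt_min)))
  vr <- cfg$cell_volume / grid$element_volume

  n0 <- initial_cell_count(cfg)
  ## --- placement ---
  occ <- matrix(0L, grid$n, grid$n)
  if (cfg$motility == "swim") {
    pos <- with_stream(streams, "placement", {
      x <- numeric(0); y <- numeric(0)
      while (length(x) < n0) {
        cx <- stats::runif(1, 0, grid$L); cy <- stats::runif(1, 0, grid$L)
        e <- element_of(grid, cx, cy)
        if (occ[e[1], e[2]] < cfg$density_cap) {
          occ[e[1], e[2]] <- occ[e[1], e[2]] + 1L
          x <- c(x, cx); y <- c(y, cy)
        }
      }
      list(x = x, y = y, occ = occ)
    })
    x <- pos$x; y <- pos$y; occ <- pos$occ
  } else {
    ## compact cluster of n0 elements around a random admissible center
    r0 <- ceiling(sqrt(n0 / pi)) + 2
    cen <- with_stream(streams, "placement",
                       stats::runif(2, r0 * grid$dx, grid$L - r0 * grid$dx))
    ce <- element_of(grid, cen[1], cen[2])
    ii <- rep(seq_len(grid$n), times = grid$n)
    jj <- rep(seq_len(grid$n), each = grid$n)
    d2 <- (ii - ce[1])^2 + (jj - ce[2])^2
    ord <- order(d2)[seq_len(n0)]
    occ[cbind(ii[ord], jj[ord])] <- 1L
    x <- (ii[ord] - 0.5) * grid$dx
    y <- (jj[ord] - 0.5) * grid$dx
  }

  ## --- heterogeneity and per-cell state ---
  ids <- seq_len(n0)
  next_id <- n0 + 1L
  if (cfg$model == "lsr") {
    pm <- lsr_par_matrix(cfg$params, n0)
    if (!is.null(cfg$het))
      pm[, cfg$het$target] <- with_stream(streams, "heterogeneity",
                                          sample_parameter(cfg$het, n0))
    st <- lsr_initial_rows(pm)
    T0_ref <- st[, "T"]
    param_value <- if (!is.null(cfg$het)) pm[, cfg$het$target]
                   else rep(NA_real_, n0)
  } else {
    rb <- if (!is.null(cfg$het))
      with_stream(streams, "heterogeneity", sample_parameter(cfg$het, n0))
    else rep(cfg$params$r_basal_mean, n0)
    st <- cbind(AHL_in = rep(0, n0), t_since = rep(-1, n0), r_basal = rb)
    pm <- NULL
    T0_ref <- rep(NA_real_, n0)
    param_value <- rb
    lp <- c(cfg$params$threshold, cfg$params$r_max, cfg$params$ramp,
            cfg$params$conductivity, cfg$params$degradation)
  }
  doubling <- with_stream(streams, "division",
                          assign_doubling_time(cfg$growth, n0))
  counter <- doubling
  qs <- rep(FALSE, n0)
  ever_active <- rep(FALSE, n0)
  field <- concentration_field(grid, cfg$ae_init)

  series <- list()
  snapshots <- list()
  field_snaps <- list()
  events <- list()
  first_act <- NULL

  lux_rate <- function(s) {
    frac <- pmin(pmax(s[, "t_since"], 0) / cfg$params$ramp, 1)
    ifelse(s[, "t_since"] >= 0,
           s[, "r_basal"] + (cfg$params$r_max - s[, "r_basal"]) * frac,
           s[, "r_basal"])
  }
  classify_now <- function() {
    if (cfg$model == "lsr")
      st[, "T"] > cfg$params$activation_fold * T0_ref
    else
      lux_rate(st) >= cfg$params$active_fold * st[, "r_basal"]
  }
  pop_table <- function(t_now) {
    if (cfg$model == "lsr")
      data.frame(time = t_now, id = ids, x = x, y = y, active = qs,
                 param_value = param_value, Ap = st[, "Ap"], T = st[, "T"])
    else
      data.frame(time = t_now, id = ids, x = x, y = y, active = qs,
                 param_value = param_value, AHL_in = st[, "AHL_in"],
                 synth_rate = lux_rate(st))
  }
  record_series <- function(t_now) {
    data.frame(time = t_now, n_cells = length(ids), n_active = sum(qs),
               frac_active = mean(qs),
               ae_total = field_total(field, grid),
               mean_signal = if (cfg$model == "lsr") mean(st[, "Ap"])
                             else mean(lux_rate(st)))
  }
  series[[1]] <- record_series(0)
  snapshots[[1]] <- pop_table(0)
  field_snaps[[1]] <- unclass(field)
  names(snapshots)[1] <- names(field_snaps)[1] <- "0"

  for (step in seq_len(n_steps)) {
    t_now <- step * dt_min
    ## (1) motility
    if (cfg$motility == "swim") {
      mv <- with_stream(streams, "motility",
                        move_swim(x, y, occ, grid, grid$dt_engine,
                                  cfg$swim_speed, cfg$swim_cv,
                                  cfg$density_cap))
      x <- mv$x; y <- mv$y; occ <- mv$counts
    }
    ## (2)+(3) per-cell model integration coupled to local elements
    e <- element_of(grid, x, y)
    lin <- (e[, 1] - 1L) + grid$n * (e[, 2] - 1L)
    if (cfg$model == "lsr") {
      res <- lsr_cells_step_cpp(st, pm, lin, unclass(field), vr, dt_min)
    } else {
      res <- lux_cells_step_cpp(st, lp, lin, unclass(field), vr, dt_min)
    }
    st <- res$states
    colnames(st) <- if (cfg$model == "lsr") c("Ai", "Ap", "M", "T")
                    else c("AHL_in", "t_since", "r_basal")
    field <- concentration_field(grid, res$field)
    if (any(!is.finite(st)) || any(!is.finite(field)))
      stop("run_simulation: non-finite state at t = ", t_now, call. = FALSE)
    ## (4) diffusion
    field <- diffuse(field, grid, grid$dt_engine)
    ## (5) divisions
    counter <- counter - dt_min
    due <- which(counter <= 0)
    for (k in due) {
      if (cfg$model == "lsr") {
        if (!is.null(cfg$het) && !cfg$inherit_param) {
          newv <- with_stream(streams, "heterogeneity",
                              sample_parameter(cfg$het, 1))
        } else newv <- param_value[k]
        new_pm <- pm[k, , drop = FALSE]
        if (!is.null(cfg$het)) new_pm[, cfg$het$target] <- newv
        pm <- rbind(pm, new_pm)
      } else {
        if (!is.null(cfg$het) && !cfg$inherit_param) {
          newv <- with_stream(streams, "heterogeneity",
                              sample_parameter(cfg$het, 1))
        } else newv <- param_value[k]
      }
      new_dt <- with_stream(streams, "division",
                            assign_doubling_time(cfg$growth, 1))
      new_state <- st[k, , drop = FALSE]
      if (cfg$model == "luxir") new_state[, "r_basal"] <- newv
      if (cfg$motility == "swim") {
        pe <- element_of(grid, x[k], y[k])
        place <- with_stream(streams, "placement",
                             swim_birth_slot(pe, occ, grid,
                                             cfg$density_cap))
        occ <- place$occ
        nx <- if (place$same) x[k] else (place$elem[1] - 0.5) * grid$dx
        ny <- if (place$same) y[k] else (place$elem[2] - 0.5) * grid$dx
      } else {
        pe <- element_of(grid, x[k], y[k])
        place <- with_stream(streams, "placement",
                             colony_placement(c(pe[1], pe[2]), occ, grid))
        occ <- place$occ
        if (nrow(place$moves) > 0) {
          for (m in seq_len(nrow(place$moves))) {
            fx <- (place$moves[m, 1] - 0.5) * grid$dx
            fy <- (place$moves[m, 2] - 0.5) * grid$dx
            idx <- which(abs(x - fx) < grid$dx / 4 &
                         abs(y - fy) < grid$dx / 4)[1]
            x[idx] <- (place$moves[m, 3] - 0.5) * grid$dx
            y[idx] <- (place$moves[m, 4] - 0.5) * grid$dx
          }
        }
        nx <- (place$daughter[1] - 0.5) * grid$dx
        ny <- (place$daughter[2] - 0.5) * grid$dx
      }
      x <- c(x, nx); y <- c(y, ny)
      st <- rbind(st, new_state)
      ids <- c(ids, next_id)
      param_value <- c(param_value, newv)
      T0_ref <- c(T0_ref, T0_ref[k])
      qs <- c(qs, qs[k])
      ever_active <- c(ever_active, ever_active[k])
      doubling <- c(doubling, new_dt)
      counter[k] <- doubling[k]
      counter <- c(counter, new_dt)
      next_id <- next_id + 1L
    }
    ## (6) classification and recording
    qs <- classify_now()
    newly <- which(qs & !ever_active)
    if (length(newly) > 0) {
      events[[length(events) + 1]] <-
        data.frame(time = t_now, id = ids[newly], x = x[newly], y = y[newly],
                   param_value = param_value[newly])
      if (is.null(first_act)) {
        first_act <- pop_table(t_now)
        if (isTRUE(cfg$stop_at_first_activation)) {
          series[[length(series) + 1]] <- record_series(t_now)
          break
        }
      }
      ever_active[newly] <- TRUE
    }
    if (step %% rec_steps == 0)
      series[[length(series) + 1]] <- record_series(t_now)
    if (step %% snap_steps == 0) {
      snapshots[[length(snapshots) + 1]] <- pop_table(t_now)
      field_snaps[[length(field_snaps) + 1]] <- unclass(field)
      names(snapshots)[length(snapshots)] <-
        names(field_snaps)[length(field_snaps)] <- format(t_now)
    }
  }

  rec <- list(config = cfg,
              series = do.call(rbind, series),
              snapshots = snapshots,
              field_snapshots = field_snaps,
              events = if (length(events)) do.call(rbind, events)
                       else data.frame(time = numeric(0), id = integer(0),
                                       x = numeric(0), y = numeric(0),
                                       param_value = numeric(0)),
              assignments = data.frame(id = ids, param = if (!is.null(cfg$het))
                                         cfg$het$target else NA_character_,
                                       value = param_value),
              first_activation = first_act,
              T0_ref = T0_ref,
              final = list(x = x, y = y, state = st, qs = qs, ids = ids))
  class(rec) <- "run_record"
  rec
}

## Swim-mode birth placement: parent's position if its element has
## capacity, otherwise a random element with capacity from rings of
## increasing radius.
swim_birth_slot <- function(parent_elem, occ, grid, cap) {
  i <- parent_elem[1]; j <- parent_elem[2]
  if (occ[i, j] < cap) {
    occ[i, j] <- occ[i, j] + 1L
    return(list(same = TRUE, elem = c(i, j), occ = occ))
  }
  n <- grid$n
  for (r in 1:max(n, 2)) {
    ii <- pmax(1, i - r):pmin(n, i + r)
    jj <- pmax(1, j - r):pmin(n, j + r)
    cand <- expand.grid(ii = ii, jj = jj)
    ring <- cand[pmax(abs(cand$ii - i), abs(cand$jj - j)) == r, ]
    free <- ring[occ[cbind(ring$ii, ring$jj)] < cap, ]
    if (nrow(free) > 0) {
      k <- if (nrow(free) == 1) 1L else sample.int(nrow(free), 1)
      occ[free$ii[k], free$jj[k]] <- occ[free$ii[k], free$jj[k]] + 1L
      return(list(same = FALSE, elem = c(free$ii[k], free$jj[k]), occ = occ))
    }
  }
  stop("swim_birth_slot: no element with capacity", call. = FALSE)
}
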