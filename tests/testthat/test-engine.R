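test_that("boundary overshoot reflects to twice the distance inside", {
  expect_equal(reflect_position(503, 500), 497)
  expect_equal(reflect_position(-3, 500), 3)
  expect_equal(reflect_position(c(250, 501.5), 500), c(250, 498.5))
  # double reflection for very long steps
  expect_equal(reflect_position(1003, 500), 3)
})

test_that("unobstructed moves land on the projected position", {
  g <- grid_spec(L = 100, dx = 2, depth = 6, D = 10)
  counts <- matrix(0L, g$n, g$n)
  counts[element_of(g, 50, 50)] <- 1L
  set.seed(1)
  mv <- move_swim(50, 50, counts, g, dt = 0.1)
  # recompute the projected position from the same draws
  set.seed(1)
  step <- rnorm(1, 20 * 0.1, 0.05 * 20 * 0.1)
  theta <- runif(1, 0, 2 * pi)
  expect_equal(mv$x, 50 + step * cos(theta))
  expect_equal(mv$y, 50 + step * sin(theta))
})

test_that("moves into a saturated element are rejected", {
  g <- grid_spec(L = 20, dx = 2, depth = 6, D = 10)
  counts <- matrix(3L, g$n, g$n)   # everything full except the cell's own
  e <- element_of(g, 5, 5)
  counts[e[1], e[2]] <- 1L
  set.seed(2)
  mv <- move_swim(5, 5, counts, g, dt = 1, cap = 3)
  # a 20 um step must leave the element, so the move is rejected
  expect_equal(mv$x, 5)
  expect_equal(mv$y, 5)
})

test_that("empirical mean step speed matches the configured speed", {
  g <- grid_spec(L = 1e6, dx = 2, depth = 6, D = 10)
  counts <- matrix(0L, 2, 2)       # unused: domain far from boundaries
  set.seed(3)
  n <- 1e5
  step <- rnorm(n, 20 * g$dt_engine, 0.05 * 20 * g$dt_engine)
  speeds <- pmax(step, 0) / g$dt_engine
  se <- sd(speeds) / sqrt(n)
  expect_lt(abs(mean(speeds) - 20), 3 * se)
})

test_that("an isolated colony cell places its daughter on a free neighbor", {
  g <- grid_spec(L = 40, dx = 2, depth = 6, D = 10)
  occ <- matrix(0L, g$n, g$n)
  occ[10, 10] <- 1L
  set.seed(4)
  pl <- colony_placement(c(10, 10), occ, g)
  expect_equal(sum(pl$occ), 2)
  expect_lte(max(abs(pl$daughter - c(10, 10))), 1)   # adjacent
  expect_false(all(pl$daughter == c(10, 10)))
  expect_equal(nrow(pl$moves), 0)
})

test_that("daughters never land on occupied elements; counts stay exact", {
  g <- grid_spec(L = 60, dx = 2, depth = 6, D = 10)
  occ <- matrix(0L, g$n, g$n)
  occ[15, 15] <- 1L
  parents <- matrix(c(15, 15), 1, 2)
  set.seed(5)
  for (div in 1:60) {
    k <- sample.int(nrow(parents), 1)
    before <- sum(occ)
    pl <- colony_placement(parents[k, ], occ, g)
    occ <- pl$occ
    expect_equal(sum(occ), before + 1)     # exactly one new occupied slot
    expect_lte(max(occ), 1L)               # never two cells per element
    parents <- rbind(parents, pl$daughter)
  }
  expect_equal(sum(occ), 61)               # N divisions -> N+1 cells
})

test_that("interior division pushes a connected chain outward", {
  g <- grid_spec(L = 40, dx = 2, depth = 6, D = 10)
  occ <- matrix(0L, g$n, g$n)
  occ[8:12, 8:12] <- 1L                    # 5x5 block, parent at center
  set.seed(6)
  pl <- colony_placement(c(10, 10), occ, g)
  expect_equal(sum(pl$occ), 26)
  expect_gt(nrow(pl$moves), 0)             # a chain moved
  # colony stays 8-connected
  idx <- which(pl$occ == 1, arr.ind = TRUE)
  visited <- rep(FALSE, nrow(idx))
  visited[1] <- TRUE
  repeat {
    grew <- FALSE
    for (a in which(visited)) for (b in which(!visited)) {
      if (max(abs(idx[a, ] - idx[b, ])) <= 1) { visited[b] <- TRUE; grew <- TRUE }
    }
    if (!grew) break
  }
  expect_true(all(visited))
})

test_that("identical configuration and seed reproduce the record exactly", {
  cfg <- run_config(model = "lsr", motility = "swim",
                    grid = grid_spec(L = 60, dx = 2, depth = 6,
                                     dt_engine = 2, D = 15),
                    het = heterogeneity_spec("basal", 0.025, median = 487.8),
                    n_init = 12, t_end = 15, seed = 42)
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  expect_identical(r1$series, r2$series)
  expect_identical(r1$final, r2$final)
  expect_identical(r1$assignments, r2$assignments)
})

test_that("swim runs respect the density cap and the domain bounds", {
  cfg <- run_config(model = "lsr", motility = "swim",
                    grid = grid_spec(L = 40, dx = 2, depth = 6,
                                     dt_engine = 2, D = 15),
                    het = NULL, n_init = 30, t_end = 30, seed = 8)
  rec <- run_simulation(cfg)
  for (sn in rec$snapshots) {
    expect_true(all(sn$x >= 0 & sn$x <= 40 & sn$y >= 0 & sn$y <= 40))
    e <- element_of(cfg$grid, sn$x, sn$y)
    counts <- table(paste(e[, 1], e[, 2]))
    expect_lte(max(counts), 3)
  }
})

test_that("luxir colony runs stay on-lattice with one cell per element", {
  cfg <- run_config(model = "luxir", motility = "colony",
                    grid = grid_spec(L = 40, dx = 2, depth = 6,
                                     dt_engine = 2, D = 5),
                    het = NULL, n_init = 10, t_end = 60, seed = 9)
  rec <- run_simulation(cfg)
  sn <- rec$snapshots[[length(rec$snapshots)]]
  expect_gt(nrow(sn), 10)                   # it grew
  e <- element_of(cfg$grid, sn$x, sn$y)
  expect_equal(max(table(paste(e[, 1], e[, 2]))), 1)
})

test_that("invalid configurations fail with field-level messages", {
  expect_error(run_config(model = "lsr", params = lux_params()),
               "lsr_params")
  expect_error(run_config(model = "luxir",
                          het = heterogeneity_spec("basal", 0.01,
                                                   median = 1)),
               "target")
  expect_error(run_config(t_end = -5), "t_end")
})

test_that("yaml config round trip and sweep seeds are distinct", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "model: lsr", "motility: swim", "n_init: 8", "t_end: 5", "seed: 11",
    "grid: {L: 40, dx: 2, depth: 6, dt_engine: 2, D: 15}",
    "het: {target: basal, sigma: 0.02, median: 487.8}"), f)
  cfg <- config_from_yaml(f)
  expect_s3_class(cfg, "run_config")
  expect_equal(cfg$grid$L, 40)
  expect_equal(cfg$het$sigma, 0.02)
  expect_error(config_from_yaml(f, list(bogus_field = 1)), "bogus_field")
  sw <- run_sweep(cfg, sigmas = c(0, 0.02), replicates = 2)
  expect_length(sw, 2)
  seeds <- unlist(lapply(sw, function(pt)
    vapply(pt, function(r) r$config$seed, numeric(1))))
  expect_equal(length(unique(seeds)), 4)
})
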