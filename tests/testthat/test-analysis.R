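test_that("an exactly linear trace has no activation point", {
  tt <- seq(0, 300, by = 2)
  expect_true(is.na(activation_time(tt, 0.5 + 0.01 * tt)))
  expect_error(activation_time(seq(0, 300, 200), c(1, 2)), "fit window")
})

test_that("detection matches a brute-force inequality scan", {
  set.seed(31)
  for (i in 1:200) {
    tt <- seq(0, 400, by = 4)
    base <- runif(1, 0.5, 5) + runif(1, 0, 0.02) * tt +
      rnorm(length(tt), 0, 0.02)
    t_star <- runif(1, 160, 360)
    f <- base + ifelse(tt > t_star, exp((tt - t_star) / 15) - 1, 0)
    expect_identical(activation_time(tt, f), brute_activation(tt, f))
  }
})

test_that("batch trajectory activation is detected after the 4-hour mark", {
  tr <- cached("batch_default", integrate_batch(t_end = 420))
  act <- activation_time(tr$time, tr$Ap)
  expect_false(is.na(act))
  expect_gt(act, 240)
  # within one sampling interval of the brute-force scan
  expect_lte(abs(act - brute_activation(tr$time, tr$Ap)), 1)
})

test_that("activated fraction matches manual counts on a built fixture", {
  flags <- list(c(FALSE, FALSE, FALSE, FALSE, FALSE),
                c(TRUE, FALSE, FALSE, FALSE, FALSE),
                c(TRUE, TRUE, TRUE, FALSE, FALSE),
                c(TRUE, TRUE, TRUE, TRUE, TRUE))
  rec <- structure(list(series = data.frame(
    time = c(0, 10, 20, 30), n_cells = 5,
    n_active = vapply(flags, sum, numeric(1)),
    frac_active = vapply(flags, mean, numeric(1)),
    ae_total = 0, mean_signal = 0)), class = "run_record")
  fa <- fraction_activated(rec)
  expect_equal(fa$frac, c(0, 0.2, 0.6, 1))
  empty <- structure(list(series = data.frame(time = 0, n_cells = 0,
                                              n_active = 0, frac_active = 0,
                                              ae_total = 0, mean_signal = 0)),
                     class = "run_record")
  expect_error(fraction_activated(empty), "empty")
})

test_that("nearest-neighbor median matches simple geometry and a loop oracle", {
  expect_equal(median_nn_distance(c(0, 10), c(0, 0)), 10)
  # square lattice with spacing s
  gpts <- expand.grid(x = seq(0, 30, 3), y = seq(0, 30, 3))
  expect_equal(median_nn_distance(gpts$x, gpts$y), 3)
  set.seed(33)
  x <- runif(200, 0, 100); y <- runif(200, 0, 100)
  oracle <- median(vapply(seq_along(x), function(i) {
    dmin <- Inf
    for (j in seq_along(x)) if (j != i) {
      d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
      if (d < dmin) dmin <- d
    }
    dmin
  }, numeric(1)))
  expect_equal(median_nn_distance(x, y), oracle)
  expect_error(median_nn_distance(1, 1), "at least 2")
})

test_that("autoinducer per induced cell is undefined until induction", {
  g <- grid_spec(L = 40, dx = 2, depth = 6, D = 10)
  rec <- structure(list(
    series = data.frame(time = c(0, 10), n_cells = c(4, 4),
                        n_active = c(0, 2), frac_active = c(0, 0.5),
                        ae_total = c(960, 960), mean_signal = 0),
    config = list(grid = g)), class = "run_record")
  out <- ae_per_induced_cell(rec)
  expect_true(is.na(out$ae_per_cell[1]))
  # uniform 0.1 uM over 40x40x6 domain shared by 2 induced cells
  expect_equal(out$ae_per_cell[2], 960 / (40 * 40 * 6) / 2)
})

test_that("center bias statistics read constructed records correctly", {
  g <- grid_spec(L = 100, dx = 2, depth = 6, D = 10)
  mk <- function(xs, ys, act) structure(list(
    first_activation = data.frame(time = 1, id = seq_along(xs), x = xs,
                                  y = ys, active = act,
                                  param_value = 1, AHL_in = 0,
                                  synth_rate = 0),
    config = list(grid = g)), class = "run_record")
  # all cells activated at once: centers coincide
  r_all <- mk(c(10, 20, 30), c(50, 50, 50), c(TRUE, TRUE, TRUE))
  cen <- induction_center_bias(list(r_all, r_all))$centers
  expect_equal(cen$colony_x, cen$induction_x)
  # activations clustered toward the x = 0 boundary
  r_edge <- mk(c(5, 10, 60, 80), c(50, 50, 50, 50),
               c(TRUE, TRUE, FALSE, FALSE))
  cen2 <- induction_center_bias(list(r_edge))$centers
  expect_lt(cen2$induction_x, cen2$colony_x)
})

test_that("first-activator statistics handle a single record", {
  rec <- structure(list(
    events = data.frame(time = c(12, 30), id = 1:2, x = 0, y = 0,
                        param_value = c(520, 470)),
    assignments = data.frame(id = 1:5, param = "basal",
                             value = c(520, 470, 480, 500, 490))),
    class = "run_record")
  st <- first_activator_stats(rec)
  expect_equal(st$first_values, 520)   # earliest event's value
  expect_equal(st$mean, 520)
  expect_length(st$population, 5)
})

test_that("local heterogeneity is 0 for uniform states, ~1 for random ones", {
  set.seed(35)
  x <- runif(800, 0, 100); y <- runif(800, 0, 100)
  expect_equal(local_heterogeneity(x, y, rep(TRUE, 800)), 0)
  for (p in c(0.2, 0.5, 0.8)) {
    a <- runif(800) < p
    sc <- local_heterogeneity(x, y, a, radius = 10)
    expect_equal(sc, 1, tolerance = 0.1)
    # invariant under relabeling
    expect_equal(local_heterogeneity(x, y, !a, radius = 10), sc)
  }
})
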