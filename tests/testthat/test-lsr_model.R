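test_that("parameter validation names the offending field", {
  expect_error(lsr_params(K_synth = -1), "K_synth")
  expect_error(lsr_params(basal = NaN), "basal")
  expect_error(lsr_params(activation_fold = 1), "activation_fold")
})

test_that("rhs rejects invalid states by name", {
  p <- lsr_params()
  s <- lsr_initial_state(p)
  s["Ai"] <- -1
  expect_error(lsr_rhs(s, p), "Ai")
  s["Ai"] <- Inf
  expect_error(lsr_rhs(s, p), "Ai")
})

test_that("with no sources and no transporters all AI-2 fluxes vanish", {
  p <- lsr_params(K_synth = 0, basal = 0)
  s <- c(Ae = 3, Ai = 0, Ap = 0, M = 0.5, T = 0)
  d <- lsr_rhs(s, p)
  expect_identical(unname(d[c("Ae", "Ai", "Ap")]), c(0, 0, 0))
})

test_that("export alone conserves AI-2 between compartments exactly", {
  p <- lsr_params(K_synth = 0, basal = 0, k_phos = 0, k_pK = 0, V_ind = 0,
                  d_Ap = 0)
  s <- c(Ae = 0.7, Ai = 4.2, Ap = 0, M = 0, T = 1)
  vr <- 1 / 24
  d <- lsr_rhs(s, p, volume_ratio = vr)
  expect_equal(unname(d["Ai"]), -p$V_ydgG * 4.2)
  expect_equal(unname(d["Ae"]), p$V_ydgG * 4.2 * vr)
  # mole balance: d(Ae)/vr + d(Ai) + d(Ap) == 0 to machine precision
  expect_equal(unname(d["Ae"]) / vr + unname(d["Ai"]) + unname(d["Ap"]), 0)
})

test_that("rhs equals an independently hand-summed derivative", {
  set.seed(42)
  p <- lsr_params()
  for (i in 1:10) {
    s <- c(Ae = runif(1, 0, 20), Ai = runif(1, 0, 80),
           Ap = runif(1, 0, 10), M = runif(1, 0, 50), T = runif(1, 0, 200))
    vr <- 1 / 24
    # written out term by term, without the registry
    exp_ <- p$V_ydgG * s[["Ai"]]
    bas <- p$basal * s[["Ae"]] / (p$K_basal + s[["Ae"]])
    ind <- p$V_ind * s[["T"]] * s[["Ae"]] / (p$K_ind + s[["Ae"]])
    kp <- p$k_phos + p$k_pK * s[["T"]]
    hill <- s[["Ap"]]^p$hill_n / (p$k2^p$hill_n + s[["Ap"]]^p$hill_n)
    expected <- c(Ae = vr * (exp_ - bas - ind),
                  Ai = p$K_synth - exp_ + bas + ind - kp * s[["Ai"]],
                  Ap = kp * s[["Ai"]] - p$d_Ap * s[["Ap"]],
                  M = p$a0 + p$a_M * hill - p$d_M * s[["M"]],
                  T = p$k_T * s[["M"]] - p$d_T * s[["T"]])
    expect_equal(lsr_rhs(s, p, vr), expected, tolerance = 1e-12)
  }
})

test_that("batch culture autoinduces with the expected signatures", {
  tr <- cached("batch_default", integrate_batch(t_end = 420))
  T0 <- lsr_initial_state()[["T"]]
  # abrupt transporter rise past the fold threshold after the 4-hour mark
  t5 <- tr$time[min(which(tr$T > 5 * T0))]
  expect_gt(t5, 240)
  # extracellular AI-2 peaks then collapses
  expect_gt(max(tr$Ae), 5)
  expect_lt(tr$Ae[nrow(tr)], 0.2 * max(tr$Ae))
  # phospho-AI-2 ends far above its uninduced level
  expect_gt(tr$Ap[nrow(tr)], 10 * tr$Ap[1])
  # mRNA rise is abrupt: from 10% to 50% of its maximum within 30 minutes
  Mmax <- max(tr$M)
  t_lo <- tr$time[min(which(tr$M > 0.1 * Mmax))]
  t_hi <- tr$time[min(which(tr$M > 0.5 * Mmax))]
  expect_lt(t_hi - t_lo, 30)
})

test_that("without AI-2 synthesis the circuit stays at its uninduced state", {
  p <- lsr_params(K_synth = 0)
  tr <- integrate_batch(p, t_end = 300)
  expect_equal(max(tr$Ap), 0, tolerance = 1e-8)
  expect_lt(max(tr$M), 1.05 * tr$M[1] + 1e-6)
})

test_that("positivity holds across a random parameter box", {
  set.seed(7)
  for (i in 1:5) {
    p <- lsr_params(K_synth = runif(1, 20, 100),
                    V_ydgG = runif(1, 4, 12),
                    basal = runif(1, 200, 800),
                    k_phos = runif(1, 0.05, 0.5),
                    d_Ap = runif(1, 4, 12))
    tr <- integrate_batch(p, t_end = 350, dt = 2)
    expect_gte(min(as.matrix(tr[, -1])), -1e-9)
  }
})

test_that("time to activation moves monotonically with each rate", {
  t5x <- function(p) {
    tr <- integrate_batch(p, t_end = 420, dt = 2)
    T0 <- lsr_initial_state(p)[["T"]]
    i <- which(tr$T > p$activation_fold * T0)
    if (length(i)) tr$time[min(i)] else Inf
  }
  base <- t5x(lsr_params())
  up <- function(nm, f) {
    p <- lsr_params(); p[[nm]] <- p[[nm]] * f; t5x(p)
  }
  # more import, synthesis or phosphorylation: earlier autoinduction
  expect_lt(up("basal", 1.1), base)
  expect_lt(up("K_synth", 1.1), base)
  expect_lt(up("k_phos", 1.1), base)
  # more export or a higher transcription threshold: later
  expect_gt(up("V_ydgG", 1.1), base)
  expect_gt(up("k2", 1.1), base)
})

test_that("identical cells sharing a pool stay identical", {
  p <- lsr_params()
  tr <- two_cell_shared_pool(p, p, t_end = 300, dt = 5)
  for (v in c("Ai", "Ap", "M", "T"))
    expect_equal(tr[[paste0(v, "_A")]], tr[[paste0(v, "_B")]],
                 tolerance = 1e-6)
})

test_that("a low-basal cell is starved by its high-basal partner", {
  pA <- lsr_params(basal = 510)
  pB <- lsr_params(basal = 300)
  tr <- two_cell_shared_pool(pA, pB, t_end = 420, dt = 2)
  T0 <- lsr_initial_state(pA)[["T"]]
  expect_true(any(tr$T_A > 5 * T0))          # cell A autoinduces
  expect_false(any(tr$T_B > 5 * lsr_initial_state(pB)[["T"]]))
  # cell B's phospho-AI-2 stagnates near its uninduced level
  expect_lt(max(tr$Ap_B), 0.05 * max(tr$Ap_A))
})

test_that("the dominant cell always activates no later than its partner", {
  pA <- lsr_params(basal = 510)
  first_t5 <- function(tt, T, T0) {
    i <- which(T > 5 * T0); if (length(i)) tt[min(i)] else Inf
  }
  for (bB in c(510, 480, 420)) {
    pB <- lsr_params(basal = bB)
    tr <- two_cell_shared_pool(pA, pB, t_end = 420, dt = 2)
    tA <- first_t5(tr$time, tr$T_A, lsr_initial_state(pA)[["T"]])
    tB <- first_t5(tr$time, tr$T_B, lsr_initial_state(pB)[["T"]])
    expect_lte(tA, tB)
  }
})

test_that("bisection for the smallest activating basal matches a scan", {
  pA <- lsr_params(basal = 510)
  b_min <- min_activating_basal(pA, lo = 300, t_end = 360, tol = 5)
  expect_true(is.finite(b_min))
  # direct scan oracle on a 5 uM/min grid
  activates <- function(b) {
    pB <- lsr_params(basal = b)
    tr <- two_cell_shared_pool(pA, pB, t_end = 360, dt = 2)
    any(tr$T_B > 5 * lsr_initial_state(pB)[["T"]])
  }
  grid <- seq(300, 510, by = 5)
  scan <- grid[min(which(vapply(grid, activates, logical(1))))]
  expect_lte(abs(b_min - scan), 5)
})

test_that("pool AI-2 is conserved when synthesis and catabolism are off", {
  # sources off: no synthesis, no phospho turnover; transcription frozen so
  # transporter dynamics cannot create or destroy AI-2 anyway
  p <- lsr_params(K_synth = 0, d_Ap = 0)
  phi <- function(t) 2.4e-4
  s0 <- c(Ae = 10, Ai = 2, Ap = 1, M = 0.1, T = 5)
  tr <- integrate_batch(p, phi, t_end = 100, dt = 1, state0 = s0)
  total <- tr$Ae + phi(0) * (tr$Ai + tr$Ap)
  expect_lt(max(abs(total - total[1])) / total[1], 1e-6)
})
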