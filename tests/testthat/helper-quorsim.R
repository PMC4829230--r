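## Shared reduced-scale study configurations and a cache so expensive
## simulation sets are computed once per test session.

## Reduced swim-study grid: 100 x 100 um, 2-um elements and an engine step
## of 2 s; D = 15 um^2/s, the largest coefficient stable on this grid at
## the full-scale 0.0667-s master step without sub-stepping.
test_grid <- function(L = 100, D = 15, dt_engine = 2) {
  grid_spec(L = L, dx = 2, depth = 6, dt_engine = dt_engine, D = D)
}

## Colony-contrast grid: slightly larger domain, strongly gradient-forming
## diffusion, slower growth so the colony stays within the domain while
## AHL accumulates.
contrast_grid <- function() grid_spec(L = 120, dx = 2, depth = 6,
                                      dt_engine = 2, D = 2)
contrast_growth <- function() growth_spec(growth_rate = log(2) / 60)

swim_cfg <- function(sigma, seed, target = "basal", t_end = 170,
                     log_base = "e", median = NULL) {
  p <- lsr_params()
  med <- if (is.null(median)) {
    if (target == "basal") 487.8 else p[[target]]
  } else median
  run_config(model = "lsr", motility = "swim", grid = test_grid(),
             het = heterogeneity_spec(target, sigma, median = med,
                                      log_base = log_base),
             n_init = 40, t_end = t_end, seed = seed)
}

.quorsim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .quorsim_cache))
    assign(key, expr, envir = .quorsim_cache)
  get(key, envir = .quorsim_cache)
}

## sigma sweep runs (3 sigma x 3 replicates) for one heterogeneity target
sigma_runs <- function(target) {
  cached(paste0("sigma_", target), {
    lapply(c(0, 0.0125, 0.025), function(sig) {
      lapply(1:3, function(s)
        run_simulation(swim_cfg(sig, seed = s, target = target)))
    })
  })
}

## LuxIR colony replicates run to first activation (center bias and
## first-activator statistics)
lux_bias_runs <- function(n = 20) {
  cached("lux_bias", {
    lapply(seq_len(n), function(s) {
      cfg <- run_config(model = "luxir", motility = "colony",
                        grid = contrast_grid(), growth = contrast_growth(),
                        het = heterogeneity_spec("r_basal", 0.0225,
                                                 median = 1,
                                                 log_base = "10"),
                        n_init = 40, t_end = 340, seed = 500 + s,
                        stop_at_first_activation = TRUE)
      run_simulation(cfg)
    })
  })
}

## Lsr colony replicates run to first activation (first-activator statistics)
lsr_first_runs <- function(n = 10) {
  cached("lsr_first", {
    lapply(seq_len(n), function(s) {
      cfg <- run_config(model = "lsr", motility = "colony",
                        grid = contrast_grid(), growth = contrast_growth(),
                        het = heterogeneity_spec("basal", 0.0225,
                                                 median = 487.8,
                                                 log_base = "10"),
                        n_init = 40, t_end = 250, seed = 700 + s,
                        stop_at_first_activation = TRUE)
      run_simulation(cfg)
    })
  })
}

## matched-config colony runs for the speckle-vs-front contrast
contrast_runs <- function() {
  cached("contrast", {
    mk <- function(model, target, median) {
      cfg <- run_config(model = model, motility = "colony",
                        grid = contrast_grid(), growth = contrast_growth(),
                        het = heterogeneity_spec(target, 0.0225,
                                                 median = median,
                                                 log_base = "10"),
                        n_init = 40, t_end = 330, seed = 3,
                        snapshot_every = 2)
      run_simulation(cfg)
    }
    list(lux = mk("luxir", "r_basal", 1),
         lsr = mk("lsr", "basal", 487.8))
  })
}

## brute-force activation-time oracle: independent of activation_time()
brute_activation <- function(time, f, window = c(12, 152)) {
  w <- time >= window[1] & time <= window[2]
  tw <- time[w]; fw <- f[w]
  b <- sum((tw - mean(tw)) * (fw - mean(fw))) / sum((tw - mean(tw))^2)
  a <- mean(fw) - b * mean(tw)
  for (i in seq_along(time)) {
    g <- a + b * time[i]
    if (f[i] - g > 2 * g) return(time[i])
  }
  NA_real_
}
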