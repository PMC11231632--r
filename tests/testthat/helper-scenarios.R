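# Shared small fixtures, built in code.

# 29-day screening protocol and a fast-drying pot: a 60 g transplant in a
# 1 L-capacity pot traverses the full SWC range within the 11-day drought.
sweep_schedule <- function() phase_schedule(9, 11, 9)

sweep_env <- function(seed = 5) {
  make_env_series(sweep_schedule(), c(24, 33), c(30, 60), 500, seed = seed)
}

sweep_pot <- function() {
  pot_state(soil_water_capacity = 1000, plant_fresh_weight = 60)
}

sim_sweep_plant <- function(theta = 35, e_max = 12, slope = 0.05,
                            noise_sd = 1, seed = 1, env = sweep_env(), ...) {
  gp <- genotype_params(e_max, theta, slope, growth_efficiency = 0.02,
                        recovery_factor = 1)
  simulate_plant(gp, env, sweep_schedule(), pot0 = sweep_pot(),
                 noise_sd = noise_sd, seed = seed, ...)
}

# A minimal synthetic weight series (no irrigation): linear loss.
linear_series <- function(n = 480, step_g = -0.3125, w0 = 3000,
                          interval = 3) {
  time_min <- seq(0, by = interval, length.out = n)
  tibble::tibble(
    time_min = time_min,
    day = time_min %/% 1440 + 1,
    hour = (time_min %% 1440) / 60,
    weight_g = w0 + step_g * (seq_len(n) - 1),
    t_air_c = 25, rh_pct = 50, par_umol_m2_s = 500,
    vpd_kpa = vpd_from_t_rh(25, 50)
  )
}

flat_meta <- function(capacity = 1000) {
  list(tare_weight = 0, soil_dry_weight = 0, soil_water_capacity = capacity,
       evap_frac = 0, plant_id = "T1", line = "test")
}

# Independent fine-grid broken-stick oracle: naive per-candidate least
# squares at `step` resolution (kept deliberately separate from the package
# implementation).
oracle_broken_stick <- function(swc, tr, step = 0.01) {
  grid <- seq(min(swc), max(swc), by = step)
  best <- list(sse = Inf, theta = NA)
  for (cc in grid) {
    x <- pmax(0, cc - swc)
    if (var(x) > 0) {
      b <- -stats::cov(x, tr) / var(x)
      if (b < 0) b <- 0
    } else {
      b <- 0
    }
    a <- mean(tr + b * x)
    sse <- sum((tr - a + b * x)^2)
    if (sse < best$sse - 1e-15) best <- list(sse = sse, theta = cc, a = a, b = b)
  }
  best
}
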