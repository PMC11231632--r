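#' Simulate one plant on a gravimetric lysimeter
#'
#' Runs a discrete water-balance simulation of pot + soil + plant on a load
#' cell under diurnal atmospheric forcing and the three-phase irrigation
#' protocol. Per sampling step:
#' \enumerate{
#'   \item potential normalized transpiration
#'     `e_pot = e_max_true * (PAR/par_ref) * (VPD/vpd_ref)` (platform units),
#'     scaled by `recovery_factor` during rewatering;
#'   \item a linear-plateau stomatal factor of soil water content:
#'     `f = 1` for `SWC >= theta_c_true`, else
#'     `max(0, 1 - decline_slope_true * (theta_c_true - SWC))`;
#'   \item transpired mass `e_pot * f * W * dt` converted to grams via
#'     18.015 g mol^-1;
#'   \item soil evaporation as a constant daylight fraction of capacity;
#'   \item plant growth `growth_efficiency * transpired * (1 - W/w_max)`
#'     (logistic damping keeps multi-week growth bounded);
#'   \item nightly refill to capacity during pre-treatment and rewatering;
#'     none during drought until the plant's own termination: at the first
#'     pre-dawn reading with SWC below the schedule's `drought_stop_swc`,
#'     nightly maintenance irrigation holds the plant at the stop SWC
#'     (full refill resumes with the rewatering phase);
#'   \item the observed weight is the true system weight plus Gaussian
#'     load-cell noise.
#' }
#' On the noise-free trajectory the water balance
#' `delta(system weight) = irrigation - transpired - evaporated + delta(plant)`
#' holds to machine precision at every step.
#'
#' @param genotype A [genotype_params()].
#' @param env An `env_series` from [make_env_series()] covering the schedule.
#' @param schedule The [phase_schedule()]; must match the one `env` was built
#'   for.
#' @param pot0 Initial [pot_state()]; must start at capacity.
#' @param noise_sd Load-cell noise standard deviation, g (default 1).
#' @param evap_frac Soil evaporation as fraction of capacity per day,
#'   daylight only (default 0.005).
#' @param w_max Carrying capacity of plant fresh weight, g.
#' @param refill_hour,predawn_hour Hour of nightly refill and of the pre-dawn
#'   reading used for the drought-termination rule.
#' @param par_ref,vpd_ref Reference forcing; defaults to the midday means of
#'   `env` (see [env_reference()]).
#' @param seed Optional integer seed for the observation noise.
#' @return Object of class `plant_series`: list with `data` (tibble:
#'   `time_min`, `day`, `hour`, `weight_g`, environment columns), `irrigation`
#'   (tibble: `time_min`, `volume_g`), `truth` (tibble: noise-free state and
#'   per-step fluxes), and `meta` (ids, genotype, pot, references,
#'   `termination_day`).
#' @export
simulate_plant <- function(genotype, env, schedule,
                           pot0 = pot_state(),
                           noise_sd = 1,
                           evap_frac = 0.005,
                           w_max = 300,
                           refill_hour = 22,
                           predawn_hour = 4,
                           par_ref = NULL, vpd_ref = NULL,
                           seed = NULL,
                           plant_id = "P001", line = NA_character_) {
  stopifnot(inherits(schedule, "phase_schedule"))
  gp <- if (inherits(genotype, "genotype_params")) genotype else do.call(genotype_params, genotype)
  n <- schedule$total_days * schedule$samples_per_day
  if (nrow(env) < n) stop("environment series shorter than the schedule")
  env <- env[seq_len(n), ]
  if (pot0$soil_water_capacity <= 0) stop("pot capacity must be positive")
  if (abs(pot0$soil_water - pot0$soil_water_capacity) > 1e-8) {
    stop("`pot0` must start at pot capacity")
  }

  refs <- env_reference(env)
  if (is.null(par_ref)) par_ref <- refs$par_ref
  if (is.null(vpd_ref)) vpd_ref <- refs$vpd_ref

  dt_min <- schedule$sampling_interval
  dt_s <- dt_min * 60
  cap <- pot0$soil_water_capacity
  base <- pot0$tare_weight + pot0$soil_dry_weight
  e_int <- gp$e_max_true / E_PLATFORM_SCALE  # platform units -> mmol s^-1 g^-1

  phase <- phase_of_day(schedule, env$day)
  is_rewater <- phase == "rewater"
  is_drought <- phase == "drought"
  demand <- (env$par_umol_m2_s / par_ref) * (env$vpd_kpa / vpd_ref)
  daylight <- env$hour >= 6 & env$hour < 18
  evap_step <- ifelse(daylight, evap_frac * cap * dt_min / 720, 0)
  # first sample at or after the scheduled hour, robust to any cadence
  m <- env$time_min %% 1440
  at_hour <- function(h) m >= h * 60 & m < h * 60 + dt_min
  is_refill <- at_hour(refill_hour) & !is_drought
  refill_in_drought <- at_hour(refill_hour) & is_drought
  is_predawn <- at_hour(predawn_hour) & is_drought

  sw <- numeric(n); pw <- numeric(n)
  transp <- numeric(n); evap <- numeric(n); irrig <- numeric(n)
  sw_i <- pot0$soil_water
  pw_i <- pot0$plant_fresh_weight
  terminated <- FALSE
  termination_day <- NA_integer_
  theta <- gp$theta_c_true
  slope <- gp$decline_slope_true
  ge <- gp$growth_efficiency
  rf <- gp$recovery_factor
  stop_swc <- schedule$drought_stop_swc

  for (i in seq_len(n)) {
    # state observed at sample i
    sw[i] <- sw_i
    pw[i] <- pw_i
    swc_i <- 100 * sw_i / cap
    if (is_predawn[i] && !terminated && swc_i < stop_swc) {
      terminated <- TRUE
      termination_day <- env$day[i]
    }
    if (is_refill[i]) {
      vol <- cap - sw_i
      if (vol > 1e-9) {
        irrig[i] <- vol
        sw_i <- cap
      }
    } else if (refill_in_drought[i] && terminated) {
      # maintenance irrigation: hold the terminated plant at the stop SWC
      # (full nightly refill resumes only with the rewatering phase)
      target <- cap * stop_swc / 100
      vol <- target - sw_i
      if (vol > 1e-9) {
        irrig[i] <- vol
        sw_i <- target
      }
    }
    if (i < n) {
      e_pot <- e_int * demand[i] * (if (is_rewater[i]) rf else 1)
      f <- if (swc_i >= theta) 1 else max(0, 1 - slope * (theta - swc_i))
      tr <- e_pot * f * pw_i * dt_s * WATER_G_PER_MMOL
      tr <- min(tr, sw_i)
      ev <- min(evap_step[i], sw_i - tr)
      dW <- ge * tr * max(0, 1 - pw_i / w_max)
      sw_i <- sw_i - tr - ev
      pw_i <- pw_i + dW
      transp[i] <- tr
      evap[i] <- ev
    }
  }

  # Irrigation at sample i happens after the observation at i, so the
  # observed weight at i excludes that volume (sw/pw are pre-refill states).
  weight_true <- base + sw + pw
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  noise <- if (noise_sd > 0) rnorm(n, 0, noise_sd) else numeric(n)

  data <- tibble::tibble(
    time_min = env$time_min,
    day = env$day,
    hour = env$hour,
    weight_g = weight_true + noise,
    t_air_c = env$t_air_c,
    rh_pct = env$rh_pct,
    par_umol_m2_s = env$par_umol_m2_s,
    vpd_kpa = env$vpd_kpa
  )
  truth <- tibble::tibble(
    time_min = env$time_min,
    day = env$day,
    hour = env$hour,
    weight_true_g = weight_true,
    soil_water_g = sw,
    plant_fw_g = pw,
    swc_pct = 100 * sw / cap,
    transp_g = transp,
    evap_g = evap,
    irrig_g = irrig
  )
  ev_idx <- which(irrig > 0)
  irrigation <- tibble::tibble(
    time_min = env$time_min[ev_idx],
    volume_g = irrig[ev_idx]
  )
  structure(
    list(
      data = data,
      irrigation = irrigation,
      truth = truth,
      meta = list(
        plant_id = plant_id, line = line,
        genotype = gp,
        tare_weight = pot0$tare_weight,
        soil_dry_weight = pot0$soil_dry_weight,
        soil_water_capacity = cap,
        par_ref = par_ref, vpd_ref = vpd_ref,
        evap_frac = evap_frac, noise_sd = noise_sd, w_max = w_max,
        refill_hour = refill_hour, predawn_hour = predawn_hour,
        termination_day = termination_day
      ),
      schedule = schedule
    ),
    class = "plant_series"
  )
}

#' @export
print.plant_series <- function(x, ...) {
  cat(sprintf(
    "<plant_series> %s (%s): %d samples over %d days, %d irrigation events\n",
    x$meta$plant_id, x$meta$line, nrow(x$data), x$schedule$total_days,
    nrow(x$irrigation)
  ))
  invisible(x)
}

#' Check the water-balance identity on the noise-free trajectory
#'
#' @param series A `plant_series` with truth attached.
#' @return Maximum absolute step-wise relative error of
#'   `delta(system weight) - (irrigation - transpired - evaporated +
#'   delta(plant))`, relative to pot capacity.
#' @export
mass_balance_error <- function(series) {
  tr <- series$truth
  n <- nrow(tr)
  dW <- diff(tr$weight_true_g)
  flux <- tr$irrig_g[-n] - tr$transp_g[-n] - tr$evap_g[-n] +
    diff(tr$plant_fw_g)
  max(abs(dW - flux)) / series$meta$soil_water_capacity
}

#' Simulate a replicated cohort of genotypes
#'
#' One plant per line x replicate, with replicate-to-replicate parameter
#' jitter (multiplicative, coefficient of variation `cv`) and distinct
#' derived noise seeds, sharing one environment series.
#'
#' @param lines Tibble of per-line parameters (columns of
#'   [barley_lines_18()]; harvest columns optional).
#' @param reps Replicates per line (>= 1).
#' @param schedule,env As in [simulate_plant()].
#' @param seed Integer seed governing jitter and observation noise.
#' @param cv Coefficient of variation of replicate parameter jitter.
#' @param ... Passed to [simulate_plant()] (e.g. `noise_sd`, `pot0`).
#' @return List of `plant_series` of length `nrow(lines) * reps`.
#' @export
make_cohort <- function(lines, reps, schedule, env, seed = 1, cv = 0.05, ...) {
  stopifnot(nrow(lines) >= 1, reps >= 1)
  withr::local_seed(as.integer(seed))
  out <- vector("list", nrow(lines) * reps)
  k <- 0
  for (li in seq_len(nrow(lines))) {
    row <- lines[li, ]
    for (r in seq_len(reps)) {
      k <- k + 1
      j <- function(x) x * max(0.5, rnorm(1, 1, cv))
      gp <- genotype_params(
        e_max_true = j(row$e_max_true),
        theta_c_true = j(row$theta_c_true),
        decline_slope_true = j(row$decline_slope_true),
        growth_efficiency = j(row$growth_efficiency),
        recovery_factor = min(1, j(row$recovery_factor)),
        strategy_label_true = row$strategy_true %||% NA_character_
      )
      child_seed <- (as.integer(seed) + 7919L * k) %% .Machine$integer.max
      out[[k]] <- simulate_plant(
        gp, env, schedule,
        seed = child_seed,
        plant_id = sprintf("P%03d_%d", li, r),
        line = row$line, ...
      )
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Long-format export of a cohort's raw observations
#'
#' @param cohort List of `plant_series`.
#' @return Tibble with columns `time_min`, `plant_id`, `line`, `weight_g`,
#'   `t_air_c`, `rh_pct`, `par_umol_m2_s`, `vpd_kpa`.
#' @export
cohort_long <- function(cohort) {
  purrr::map_dfr(cohort, function(s) {
    dplyr::mutate(s$data,
                  plant_id = s$meta$plant_id, line = s$meta$line,
                  .after = "time_min")
  })
}

#' Irrigation log of a cohort
#' @param cohort List of `plant_series`.
#' @return Tibble `time_min`, `plant_id`, `volume_g`.
#' @export
cohort_irrigation <- function(cohort) {
  purrr::map_dfr(cohort, function(s) {
    dplyr::mutate(s$irrigation, plant_id = s$meta$plant_id, .after = "time_min")
  })
}

#' Ground-truth parameter sidecar of a cohort
#' @param cohort List of `plant_series`.
#' @return Tibble, one row per plant, with the realized genotype parameters.
#' @export
cohort_truth <- function(cohort) {
  purrr::map_dfr(cohort, function(s) {
    gp <- s$meta$genotype
    tibble::tibble(
      plant_id = s$meta$plant_id, line = s$meta$line,
      e_max_true = gp$e_max_true, theta_c_true = gp$theta_c_true,
      decline_slope_true = gp$decline_slope_true,
      growth_efficiency = gp$growth_efficiency,
      recovery_factor = gp$recovery_factor,
      strategy_true = gp$strategy_label_true,
      termination_day = s$meta$termination_day %||% NA_integer_
    )
  })
}
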