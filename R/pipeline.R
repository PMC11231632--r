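#' Scenario configuration
#'
#' Bundles every tunable of a simulation-plus-analysis run. Two stock
#' scenarios mirror the two protocols the package emulates:
#' `"81line"` — 29 days (9 pre + 11 drought + 9 rewatering), 81 lines,
#' no replication, T 24-33 degC, RH 30-60 %;
#' `"18line"` — 55 days (11 + 15 + 29), 18 lines, replicated, T 20-35 degC,
#' RH 20-80 %.
#'
#' @param scenario `"18line"`, `"81line"` or `"custom"`.
#' @param seed Integer master seed; every stochastic stage derives from it.
#' @param lines Line parameter table; defaults per scenario.
#' @param reps Replicates per line; defaults 5 (18line) / 1 (81line).
#' @param schedule A [phase_schedule()]; defaults per scenario.
#' @param day_t_range,day_rh_range,par_peak,env_jitter Environment forcing.
#' @param noise_sd Load-cell noise sd, g.
#' @param evap_frac Daily soil evaporation fraction of capacity.
#' @param pot0 Initial [pot_state()].
#' @param w_max Plant fresh-weight carrying capacity, g.
#' @param cv Replicate parameter jitter CV.
#' @param dry_frac,husk_frac Synthetic harvest allocation.
#' @param const [extraction_constants()].
#' @param windows Metric day windows; `NULL` selects stable windows from the
#'   simulated environment at run time.
#' @param alpha Significance level for the statistical stage.
#' @return List of class `run_config`.
#' @export
scenario_config <- function(scenario = c("18line", "81line", "custom"),
                            seed = 1,
                            lines = NULL, reps = NULL, schedule = NULL,
                            day_t_range = NULL, day_rh_range = NULL,
                            par_peak = 500, env_jitter = 0.1,
                            noise_sd = 1, evap_frac = 0.005,
                            pot0 = pot_state(), w_max = 300, cv = 0.05,
                            dry_frac = 0.30, husk_frac = 0.12,
                            const = extraction_constants(),
                            windows = NULL, alpha = 0.05) {
  scenario <- match.arg(scenario)
  if (scenario == "18line") {
    schedule <- schedule %||% phase_schedule(11, 15, 29)
    lines <- lines %||% barley_lines_18()
    reps <- reps %||% 5
    day_t_range <- day_t_range %||% c(20, 35)
    day_rh_range <- day_rh_range %||% c(20, 80)
    windows <- windows %||% metric_windows()
  } else if (scenario == "81line") {
    schedule <- schedule %||% phase_schedule(9, 11, 9)
    lines <- lines %||% barley_lines(81)
    reps <- reps %||% 1
    day_t_range <- day_t_range %||% c(24, 33)
    day_rh_range <- day_rh_range %||% c(30, 60)
  } else {
    if (is.null(schedule) || is.null(lines) || is.null(reps)) {
      stop("custom scenarios must provide `schedule`, `lines` and `reps`")
    }
    day_t_range <- day_t_range %||% c(24, 33)
    day_rh_range <- day_rh_range %||% c(30, 60)
  }
  structure(list(
    scenario = scenario, seed = as.integer(seed), lines = lines,
    reps = reps, schedule = schedule,
    day_t_range = day_t_range, day_rh_range = day_rh_range,
    par_peak = par_peak, env_jitter = env_jitter,
    noise_sd = noise_sd, evap_frac = evap_frac, pot0 = pot0, w_max = w_max,
    cv = cv, dry_frac = dry_frac, husk_frac = husk_frac,
    const = const, windows = windows, alpha = alpha
  ), class = "run_config")
}

# Library-free polynomial hash of the resolved configuration, for the run
# report.
.config_hash <- function(cfg) {
  s <- paste(deparse(cfg), collapse = "\n")
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483647
  sprintf("%08x", h)
}

#' Metric windows chosen from stable atmospheric demand
#'
#' Picks the most stable consecutive window (see [select_stable_window()])
#' in the pre-treatment and rewatering phases and derives the full
#' metric-window set. The drought window is always the final `k` days of
#' the drought phase: pots start at capacity, so the stomatal contrast
#' between lines only develops late in the drydown, and an early window
#' would compare lines before any of them is water limited.
#'
#' @param env An `env_series`.
#' @param schedule The matching [phase_schedule()].
#' @param k Window length, days.
#' @return A [metric_windows()] list.
#' @export
auto_windows <- function(env, schedule, k = 5) {
  k <- min(k, schedule$pre_days, schedule$drought_days, schedule$rewater_days)
  pre_w <- select_stable_window(env, phase_days(schedule, "pre"), k)
  dr_w <- tail(phase_days(schedule, "drought"), k)
  rw_w <- select_stable_window(env, phase_days(schedule, "rewater"), k)
  metric_windows(
    vigor_pre = pre_w, dt_pre = pre_w, dt_drought = dr_w, dt_rewater = rw_w,
    resilience_rewater = rw_w,
    recovery_rewater = rw_w[seq_len(max(1, length(rw_w) - 1))],
    recovery_drought = dr_w
  )
}

#' Simulate a scenario
#'
#' @param config A [scenario_config()].
#' @return List: `env`, `cohort`, `harvest`, `schedule`, `windows`.
#' @export
simulate_scenario <- function(config) {
  stopifnot(inherits(config, "run_config"))
  env <- make_env_series(
    config$schedule, config$day_t_range, config$day_rh_range,
    config$par_peak, config$env_jitter, seed = config$seed
  )
  cohort <- make_cohort(
    config$lines, config$reps, config$schedule, env,
    seed = config$seed + 1L, cv = config$cv,
    pot0 = config$pot0, noise_sd = config$noise_sd,
    evap_frac = config$evap_frac, w_max = config$w_max
  )
  harvest <- simulate_harvest(cohort, config$lines, config$dry_frac,
                              config$husk_frac)
  windows <- config$windows %||% auto_windows(env, config$schedule)
  list(env = env, cohort = cohort, harvest = harvest,
       schedule = config$schedule, windows = windows)
}

#' Run the full analysis pipeline
#'
#' Simulate (or accept) raw data, extract daily traits, fit the critical
#' soil-water-content breakpoints, assemble line metrics, and run the
#' statistical stage (cross-phase correlations, Tukey letter displays,
#' strategy classification, rank shifts). Optionally writes every table as
#' CSV plus a JSON run report.
#'
#' @param config A [scenario_config()].
#' @param sim Optional pre-built output of [simulate_scenario()]; simulated
#'   from `config` when absent.
#' @param out_dir Optional output directory.
#' @param include_raw Also write the long-format raw export (large).
#' @return List of class `run_result`: `daily`, `theta`, `metrics`,
#'   `correlations`, `letters`, `strategy`, `ranks`, `windows`, `report`.
#' @export
run_pipeline <- function(config, sim = NULL, out_dir = NULL,
                         include_raw = FALSE) {
  stopifnot(inherits(config, "run_config"))
  sim <- sim %||% simulate_scenario(config)
  daily <- extract_cohort_traits(sim$cohort, config$const)
  theta <- theta_by_cohort(daily)
  metrics <- build_metrics(daily, sim$harvest, theta, sim$windows)
  correlations <- phase_correlations(metrics)
  letters <- NULL
  if (config$reps >= 2) {
    letters <- purrr::map(
      list(dt_pre = sim$windows$dt_pre, dt_drought = sim$windows$dt_drought,
           dt_rewater = sim$windows$dt_rewater),
      function(w) {
        per_plant <- .window_mean(daily, w, "dt_g")
        anova_tukey_letters(per_plant$value, per_plant$line, config$alpha)
      })
  }
  strategy <- classify_strategy(metrics)
  ranks <- rank_shift_table(metrics)
  report <- list(
    scenario = config$scenario, seed = config$seed,
    config_hash = .config_hash(config),
    n_plants = length(sim$cohort),
    n_plant_days = nrow(daily),
    n_lines = nrow(metrics),
    n_invalid_fits = sum(!theta$valid),
    n_flagged_days = sum(daily$flag_missing),
    n_clipped_days = sum(daily$clipped, na.rm = TRUE),
    letters_computed = !is.null(letters)
  )
  out <- structure(list(
    daily = daily, theta = theta, metrics = metrics,
    correlations = correlations, letters = letters, strategy = strategy,
    ranks = ranks, windows = sim$windows, report = report
  ), class = "run_result")
  if (!is.null(out_dir)) {
    write_run_outputs(out, config, sim, out_dir, include_raw = include_raw)
  }
  out
}

#' Write pipeline outputs as CSV + JSON
#'
#' @param result A `run_result`.
#' @param config The [scenario_config()] used.
#' @param sim The simulation bundle (for the optional raw export).
#' @param out_dir Output directory (created if needed).
#' @param include_raw Write the long raw export and irrigation log.
#' @return `out_dir`, invisibly.
#' @export
write_run_outputs <- function(result, config, sim = NULL, out_dir,
                              include_raw = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name) readr::write_csv(x, file.path(out_dir, name))
  wr(result$daily, "daily_traits.csv")
  wr(result$theta, "theta_fits.csv")
  wr(result$metrics, "metrics.csv")
  wr(result$correlations, "correlations.csv")
  wr(result$strategy, "strategy.csv")
  wr(result$ranks, "rank_shifts.csv")
  if (!is.null(result$letters)) {
    for (nm in names(result$letters)) {
      wr(result$letters[[nm]], paste0("letters_", nm, ".csv"))
    }
  }
  if (include_raw && !is.null(sim)) {
    wr(cohort_long(sim$cohort), "raw_long.csv")
    wr(cohort_irrigation(sim$cohort), "irrigation_log.csv")
    wr(cohort_truth(sim$cohort), "truth_params.csv")
  }
  jsonlite::write_json(result$report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(
    list(scenario = config$scenario, seed = config$seed,
         config_hash = .config_hash(config)),
    file.path(out_dir, "run_config.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Rebuild a plant series from CSV exports
#'
#' Inverse of [cohort_long()] + [cohort_irrigation()] for one plant: accepts
#' the long-format raw schema and pot metadata and returns an object the
#' extraction stage consumes like a simulated series (without truth).
#'
#' @param raw Long-format tibble (columns `time_min`, `plant_id`, `line`,
#'   `weight_g`, `t_air_c`, `rh_pct`, `par_umol_m2_s`, `vpd_kpa`).
#' @param plant_id Plant to extract.
#' @param meta Pot metadata list: `tare_weight`, `soil_dry_weight`,
#'   `soil_water_capacity`, optionally `evap_frac`.
#' @param schedule Optional [phase_schedule()].
#' @param irrigation Optional irrigation log tibble (`time_min`, `plant_id`,
#'   `volume_g`).
#' @return A `plant_series` (with `truth = NULL`).
#' @export
as_plant_series <- function(raw, plant_id, meta, schedule = NULL,
                            irrigation = NULL) {
  d <- dplyr::filter(raw, .data$plant_id == !!plant_id)
  if (nrow(d) == 0) stop("plant_id not present in `raw`")
  line <- d$line[1]
  d <- dplyr::select(d, -"plant_id", -"line") |>
    dplyr::mutate(day = .data$time_min %/% 1440 + 1,
                  hour = (.data$time_min %% 1440) / 60,
                  .after = "time_min")
  irr <- NULL
  if (!is.null(irrigation)) {
    irr <- dplyr::filter(irrigation, .data$plant_id == !!plant_id) |>
      dplyr::select("time_min", "volume_g")
  }
  meta$plant_id <- plant_id
  meta$line <- line
  structure(list(data = d, irrigation = irr, truth = NULL, meta = meta,
                 schedule = schedule),
            class = "plant_series")
}
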