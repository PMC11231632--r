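#' Vapor pressure deficit from air temperature and relative humidity
#'
#' Computes VPD (kPa) using the Tetens saturation-vapor-pressure form with
#' FAO-56 constants: `es(T) = 0.6108 * exp(17.27 * T / (T + 237.3))` and
#' `vpd = es(T) * (1 - RH/100)`.
#'
#' @param t_air_c Air temperature in degrees Celsius, within \[-20, 60\].
#' @param rh_pct Relative humidity in percent, within \[0, 100\].
#' @return VPD in kPa (non-negative), vectorized over both arguments.
#' @examples
#' vpd_from_t_rh(25, 100)  # saturated air: 0
#' vpd_from_t_rh(20, 50)   # ~1.169 kPa
#' @export
vpd_from_t_rh <- function(t_air_c, rh_pct) {
  if (any(!is.finite(t_air_c)) || any(t_air_c < -20 | t_air_c > 60)) {
    stop("air temperature out of supported range [-20, 60] degC")
  }
  if (any(!is.finite(rh_pct)) || any(rh_pct < 0 | rh_pct > 100)) {
    stop("relative humidity must lie in [0, 100] %")
  }
  es <- 0.6108 * exp(17.27 * t_air_c / (t_air_c + 237.3))
  pmax(0, es * (1 - rh_pct / 100))
}

#' Simulate diurnal atmospheric forcing for a lysimeter experiment
#'
#' Builds the environment series driving the water-balance simulator:
#' a half-sine diurnal course of temperature and photosynthetically active
#' radiation (PAR) between 06:00 and 18:00 with midday peak, relative
#' humidity in anti-phase with temperature, and seeded day-to-day jitter of
#' the diurnal amplitudes. VPD is derived per sample via [vpd_from_t_rh()].
#'
#' @param schedule A [phase_schedule()].
#' @param day_t_range Length-2 numeric, night minimum and midday maximum air
#'   temperature (degC).
#' @param day_rh_range Length-2 numeric, midday minimum and night maximum
#'   relative humidity (%).
#' @param par_peak Clear-day midday PAR, umol m^-2 s^-1.
#' @param jitter Coefficient of day-to-day amplitude jitter (0 disables);
#'   each day's temperature/RH/PAR amplitude is scaled by
#'   `1 - jitter * U(0,1)` independently.
#' @param seed Optional integer seed; identical seeds give identical series.
#' @return A tibble of class `env_series` with one row per sample:
#'   `time_min`, `day`, `hour`, `t_air_c`, `rh_pct`, `par_umol_m2_s`,
#'   `vpd_kpa`. The schedule is attached as attribute `"schedule"`.
#' @export
make_env_series <- function(schedule,
                            day_t_range = c(24, 33),
                            day_rh_range = c(30, 60),
                            par_peak = 500,
                            jitter = 0.1,
                            seed = NULL) {
  stopifnot(inherits(schedule, "phase_schedule"),
            length(day_t_range) == 2, length(day_rh_range) == 2,
            day_t_range[2] >= day_t_range[1],
            day_rh_range[2] >= day_rh_range[1],
            par_peak > 0, jitter >= 0, jitter < 1)

  n_day <- schedule$total_days
  spd <- schedule$samples_per_day
  time_min <- seq(0, n_day * 1440 - 1, by = schedule$sampling_interval)
  day <- time_min %/% 1440L + 1L
  hour <- (time_min %% 1440) / 60

  jit <- function(u) 1 - jitter * u
  if (!is.null(seed)) {
    withr::local_seed(as.integer(seed))
  }
  jt <- jit(runif(n_day))
  jr <- jit(runif(n_day))
  jp <- jit(runif(n_day))

  sun <- ifelse(hour >= 6 & hour < 18, sin(pi * (hour - 6) / 12), 0)

  t_amp <- (day_t_range[2] - day_t_range[1]) * jt[day]
  rh_amp <- (day_rh_range[2] - day_rh_range[1]) * jr[day]
  t_air <- day_t_range[1] + t_amp * sun
  rh <- day_rh_range[2] - rh_amp * sun
  par <- par_peak * jp[day] * sun

  out <- tibble::tibble(
    time_min = time_min,
    day = day,
    hour = hour,
    t_air_c = t_air,
    rh_pct = rh,
    par_umol_m2_s = par,
    vpd_kpa = vpd_from_t_rh(t_air, rh)
  )
  stopifnot(nrow(out) == n_day * spd)
  attr(out, "schedule") <- schedule
  class(out) <- c("env_series", class(out))
  out
}

#' Midday reference forcing of an environment series
#'
#' The simulator expresses transpirational demand relative to a reference
#' forcing; by convention the reference is the mean PAR and mean VPD over the
#' midday window across all days, so that a well-watered plant's midday
#' normalized transpiration sits at its genotype maximum.
#'
#' @param env An `env_series`.
#' @param midday Length-2 numeric, start and end hour of the midday window.
#' @return List with `par_ref` and `vpd_ref`.
#' @export
env_reference <- function(env, midday = c(11, 14)) {
  mid <- env$hour >= midday[1] & env$hour < midday[2]
  stopifnot(any(mid))
  list(par_ref = mean(env$par_umol_m2_s[mid]),
       vpd_ref = mean(env$vpd_kpa[mid]))
}
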