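#' Extraction constants
#'
#' Conventions of the trait-extraction stage, overridable per call:
#' midday window 11:00-14:00, pre-dawn averaging window 02:00-05:00,
#' weight smoothing over 5 samples (15 min at the default cadence),
#' irrigation jump threshold 20 g, VPD floor 0.1 kPa, and the daily soil
#' evaporation allowance as a fraction of pot capacity.
#'
#' @param midday Length-2 hours of the midday aggregation window.
#' @param fit_window Length-2 hours of the tighter solar-noon window whose
#'   (SWC, E) pairs feed the breakpoint fit; on fast-drying days SWC falls
#'   by several points across the full midday window, which would smear the
#'   breakpoint.
#' @param predawn Length-2 hours of the pre-dawn averaging window.
#' @param smoothing_window Centered moving-average width, samples (odd).
#' @param jump_threshold Irrigation detection threshold, g.
#' @param vpd_floor Minimum VPD (kPa) for conductance; below it GSc is
#'   flagged missing rather than allowed to blow up.
#' @param evap_frac Daily soil-evaporation allowance as fraction of pot
#'   capacity (subtracted from daily transpiration and, as a daylight rate,
#'   from momentary transpiration).
#' @param p_atm Atmospheric pressure, kPa.
#' @return Named list of constants.
#' @export
extraction_constants <- function(midday = c(11, 14),
                                 fit_window = c(12, 13),
                                 predawn = c(2, 5),
                                 smoothing_window = 5,
                                 jump_threshold = 20,
                                 vpd_floor = 0.1,
                                 evap_frac = 0.005,
                                 p_atm = P_ATM_KPA) {
  stopifnot(smoothing_window >= 1)
  if (smoothing_window %% 2 == 0) smoothing_window <- smoothing_window + 1
  list(midday = midday, fit_window = fit_window, predawn = predawn,
       smoothing_window = smoothing_window,
       jump_threshold = jump_threshold, vpd_floor = vpd_floor,
       evap_frac = evap_frac, p_atm = p_atm)
}

# Pot metadata needed by the extraction stage; simulated series carry it in
# $meta, real exports supply it explicitly.
.series_meta <- function(series, meta = NULL) {
  if (!is.null(meta)) return(meta)
  if (inherits(series, "plant_series")) return(series$meta)
  stop("pot metadata (tare_weight, soil_dry_weight, soil_water_capacity) required")
}

.series_data <- function(series) {
  if (inherits(series, "plant_series")) series$data else series
}

.series_events <- function(series, jump_threshold) {
  if (inherits(series, "plant_series") && !is.null(series$irrigation) &&
      nrow(series$irrigation) > 0) {
    dplyr::mutate(series$irrigation, detected = FALSE)
  } else {
    detect_irrigation_events(series, jump_threshold)
  }
}

# Centered moving average with symmetrically shrinking half-width at segment
# edges (preserves linear trends exactly, including at the ends).
.smooth_symmetric <- function(w, half) {
  n <- length(w)
  if (n == 0) return(w)
  k <- seq_len(n)
  h <- pmin(half, k - 1, n - k)
  cs <- c(0, cumsum(w))
  (cs[k + h + 1] - cs[k - h]) / (2 * h + 1)
}

# Shared preprocessing: irrigation events, segment ids (segments are maximal
# irrigation-free runs), smoothed weights.
.prep_series <- function(series, const = extraction_constants()) {
  d <- .series_data(series)
  n <- nrow(d)
  if (const$smoothing_window > n) stop("smoothing window larger than series")
  events <- .series_events(series, const$jump_threshold)
  # event at time t: refill occurs between the sample at t and the next one
  ev_idx <- match(events$time_min, d$time_min)
  ev_idx <- ev_idx[!is.na(ev_idx) & ev_idx < n]
  seg <- cumsum(c(1L, as.integer(seq_len(n - 1) %in% ev_idx)))
  w <- d$weight_g
  if (anyNA(w)) {
    ok <- !is.na(w)
    w[!ok] <- stats::approx(d$time_min[ok], w[ok], xout = d$time_min[!ok],
                            rule = 2)$y
  }
  half <- (const$smoothing_window - 1) / 2
  w_s <- unlist(lapply(split(w, seg), .smooth_symmetric, half = half),
                use.names = FALSE)
  list(d = d, w_s = w_s, seg = seg, events = events, n = n,
       missing = is.na(d$weight_g))
}

#' Momentary whole-plant transpiration rate
#'
#' Transpiration rate as the negative slope of the smoothed weight series on
#' irrigation-free intervals (centered difference), minus the configured
#' daylight soil-evaporation allowance, floored at zero and converted from
#' g s^-1 to mmol s^-1 (18.015 g mol^-1). Night samples are retained but
#' flagged; samples at segment edges (adjacent to irrigation events or the
#' series ends) are masked `NA`.
#'
#' @param series A `plant_series` or raw data frame (see
#'   [detect_irrigation_events()] for the accepted columns; `hour` required).
#' @param const [extraction_constants()].
#' @param meta Pot metadata list (`soil_water_capacity`, optionally
#'   `evap_frac`); taken from the series when simulated.
#' @return Tibble: `time_min`, `day`, `hour`, `tr_mmol_s`, `night`, `masked`.
#' @export
momentary_transpiration <- function(series, const = extraction_constants(),
                                    meta = NULL) {
  meta <- .series_meta(series, meta)
  p <- .prep_series(series, const)
  d <- p$d; n <- p$n
  tr_g_s <- rep(NA_real_, n)
  t_s <- d$time_min * 60
  interior <- c(FALSE, p$seg[-c(1, 2)] == p$seg[-c(n - 1, n)], FALSE)
  idx <- which(interior)
  tr_g_s[idx] <- -(p$w_s[idx + 1] - p$w_s[idx - 1]) / (t_s[idx + 1] - t_s[idx - 1])
  daylight <- d$hour >= 6 & d$hour < 18
  evap_frac <- meta$evap_frac %||% const$evap_frac
  evap_rate <- evap_frac * meta$soil_water_capacity / (720 * 60)
  tr_g_s[daylight] <- tr_g_s[daylight] - evap_rate
  tibble::tibble(
    time_min = d$time_min, day = d$day, hour = d$hour,
    tr_mmol_s = pmax(0, tr_g_s) / WATER_G_PER_MMOL,
    # unfloored companion: flooring each noisy sample at zero would bias
    # window means upward when the true rate is near zero, so aggregates
    # are computed from the signed rate and floored afterwards
    tr_signed_mmol_s = tr_g_s / WATER_G_PER_MMOL,
    night = !daylight,
    masked = !interior
  )
}

#' Daily transpiration from day-level weight accounting
#'
#' `DT(day)` is the summed net weight decline over the irrigation-free
#' segments of the day (smoothed series; irrigation jumps excluded), minus
#' the daily soil-evaporation allowance, floored at zero. Days with more than
#' 20 % missing samples are flagged.
#'
#' @inheritParams momentary_transpiration
#' @return Tibble: `day`, `dt_g`, `n_samples`, `n_missing`, `flag_missing`.
#' @export
daily_transpiration <- function(series, const = extraction_constants(),
                                meta = NULL) {
  meta <- .series_meta(series, meta)
  p <- .prep_series(series, const)
  evap_frac <- meta$evap_frac %||% const$evap_frac
  allowance <- evap_frac * meta$soil_water_capacity
  spd <- max(table(p$d$day))
  tibble::tibble(day = p$d$day, seg = p$seg, w_s = p$w_s,
                 missing = p$missing) |>
    dplyr::group_by(.data$day, .data$seg) |>
    dplyr::summarise(decline = dplyr::first(.data$w_s) - dplyr::last(.data$w_s),
                     n = dplyr::n(), n_missing = sum(.data$missing),
                     .groups = "drop") |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(
      dt_g = pmax(0, sum(.data$decline) - allowance),
      n_samples = sum(.data$n),
      n_missing = sum(.data$n_missing),
      .groups = "drop"
    ) |>
    dplyr::mutate(flag_missing = .data$n_missing > 0.2 * spd)
}

# Pre-dawn smoothed weight per day (mean over the pre-dawn window).
.predawn_weight <- function(p, const) {
  pd <- p$d$hour >= const$predawn[1] & p$d$hour < const$predawn[2]
  tibble::tibble(day = p$d$day[pd], w = p$w_s[pd]) |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(predawn_w = mean(.data$w), .groups = "drop")
}

# Days whose pre-dawn reading follows a refill to capacity: an irrigation
# event within 10 h before the pre-dawn window AND a pre-dawn weight
# consistent with a full pot (implied plant weight positive) — partial
# maintenance irrigation (e.g. holding a terminated plant at the drought
# stop SWC) must not count. Day 1 is at capacity by protocol (pots mounted
# fully irrigated).
.capacity_days <- function(p, const, days, predawn_w, full_offset) {
  pd_min <- (days - 1) * 1440 + const$predawn[1] * 60
  vapply(seq_along(days), function(i) {
    (days[i] == 1 ||
       any(p$events$time_min >= pd_min[i] - 600 &
             p$events$time_min < pd_min[i])) &&
      predawn_w[i] - full_offset > 0
  }, logical(1))
}

#' Calculated plant weight (CPW) per day
#'
#' On days whose pre-dawn reading follows a refill to capacity
#' (pre-treatment, rewatering, post-termination drought days),
#' `CPW = predawn weight - tare - dry soil - capacity water`. On drought days
#' without refill, CPW is carried forward by water-balance bookkeeping:
#' `CPW(d) = CPW(last capacity day) + ge_est * sum(DT)` over the intervening
#' days, where `ge_est` is the plant's own pre-treatment regression (through
#' the origin) of day-to-day CPW change on daily transpiration.
#'
#' @inheritParams momentary_transpiration
#' @param schedule Optional [phase_schedule()] (taken from a `plant_series`).
#' @return Tibble: `day`, `cpw_g`, `cpw_gain_g`, `capacity_day`; the
#'   estimated growth efficiency is attached as attribute `"ge_est"`.
#' @export
estimate_plant_weight <- function(series, const = extraction_constants(),
                                  meta = NULL, schedule = NULL) {
  meta <- .series_meta(series, meta)
  if (is.null(schedule) && inherits(series, "plant_series")) {
    schedule <- series$schedule
  }
  if (is.null(meta$tare_weight) || is.null(meta$soil_dry_weight) ||
      is.null(meta$soil_water_capacity)) {
    stop("pot metadata incomplete: tare, dry soil and capacity are required")
  }
  p <- .prep_series(series, const)
  dt_tbl <- daily_transpiration(series, const, meta)
  pw <- .predawn_weight(p, const)
  days <- pw$day
  offset <- meta$tare_weight + meta$soil_dry_weight + meta$soil_water_capacity
  capacity_day <- .capacity_days(p, const, days, pw$predawn_w, offset)
  cpw <- ifelse(capacity_day, pw$predawn_w - offset, NA_real_)

  # growth efficiency from consecutive pre-treatment capacity-day pairs
  pre_days <- if (!is.null(schedule)) phase_days(schedule, "pre") else days
  pair <- which(capacity_day & c(FALSE, capacity_day[-length(days)]) &
                  days %in% pre_days & days >= 2)
  dcpw <- cpw[pair] - cpw[pair - 1]
  dtp <- dt_tbl$dt_g[match(days[pair] - 1, dt_tbl$day)]
  ok <- is.finite(dcpw) & is.finite(dtp) & dtp > 0
  ge_est <- if (sum(ok) >= 3) {
    sum(dcpw[ok] * dtp[ok]) / sum(dtp[ok]^2)
  } else {
    cap_idx <- which(capacity_day)
    span_dt <- sum(dt_tbl$dt_g[dt_tbl$day < max(days[cap_idx])])
    if (length(cap_idx) >= 2 && span_dt > 0) {
      (cpw[max(cap_idx)] - cpw[min(cap_idx)]) / span_dt
    } else 0
  }
  ge_est <- max(0, ge_est)

  # carry CPW through non-capacity (drought) days
  for (i in seq_along(days)) {
    if (!capacity_day[i]) {
      prev_cap <- max(which(capacity_day[seq_len(i - 1)]), -Inf)
      if (!is.finite(prev_cap)) next
      between <- dt_tbl$day >= days[prev_cap] & dt_tbl$day < days[i]
      cpw[i] <- cpw[prev_cap] + ge_est * sum(dt_tbl$dt_g[between])
    }
  }
  tibble::tibble(
    day = days,
    cpw_g = cpw,
    cpw_gain_g = c(NA_real_, diff(cpw)),
    capacity_day = capacity_day
  ) |> structure(ge_est = ge_est)
}

#' Soil water content per sample
#'
#' `SWC(t) = 100 * (weight(t) - tare - dry soil - CPW(day)) / capacity`,
#' computed on the smoothed weight series and clipped to \[0, 100\] with a
#' clip flag.
#'
#' @inheritParams estimate_plant_weight
#' @param cpw Output of [estimate_plant_weight()] (computed if missing).
#' @return Tibble: `time_min`, `day`, `hour`, `swc_pct`, `clipped`.
#' @export
soil_water_content <- function(series, cpw = NULL,
                               const = extraction_constants(), meta = NULL) {
  meta <- .series_meta(series, meta)
  if (meta$soil_water_capacity <= 0) stop("capacity must be positive")
  if (is.null(cpw)) cpw <- estimate_plant_weight(series, const, meta)
  p <- .prep_series(series, const)
  cpw_day <- cpw$cpw_g[match(p$d$day, cpw$day)]
  raw <- 100 * (p$w_s - meta$tare_weight - meta$soil_dry_weight - cpw_day) /
    meta$soil_water_capacity
  tibble::tibble(
    time_min = p$d$time_min, day = p$d$day, hour = p$d$hour,
    swc_pct = pmin(100, pmax(0, raw)),
    clipped = is.finite(raw) & (raw < 0 | raw > 100)
  )
}

#' Canopy stomatal conductance from normalized transpiration and VPD
#'
#' `GSc = E / (VPD / P_atm)`; below the VPD floor the value is missing
#' (flagged by `NA`) rather than allowed to diverge.
#'
#' @param e Normalized transpiration, platform units (1e-3 mmol s^-1 g^-1).
#' @param vpd_kpa Vapor pressure deficit, kPa.
#' @param p_atm Atmospheric pressure, kPa.
#' @param vpd_floor Minimum usable VPD, kPa.
#' @return GSc in platform units, `NA` where `vpd_kpa < vpd_floor`.
#' @examples
#' canopy_conductance(1, 101.3 / 100)  # 100
#' @export
canopy_conductance <- function(e, vpd_kpa, p_atm = P_ATM_KPA, vpd_floor = 0.1) {
  ifelse(vpd_kpa >= vpd_floor, e / (vpd_kpa / p_atm), NA_real_)
}

#' Select the most stable k-day window of a phase
#'
#' Returns the `k` consecutive days minimizing the summed squared
#' coefficients of variation of the daily-mean VPD and daily-mean PAR,
#' with ties broken toward the earliest start. This mirrors the practice of
#' analyzing each phase over the five consecutive days with the most stable
#' atmospheric demand.
#'
#' @param env An `env_series`.
#' @param days Integer vector of consecutive day indices (one phase).
#' @param k Window length in days.
#' @return Integer vector of `k` consecutive day indices.
#' @export
select_stable_window <- function(env, days, k = 5) {
  days <- sort(unique(as.integer(days)))
  if (length(days) < k) stop("phase shorter than the window length")
  if (any(diff(days) != 1)) stop("`days` must be consecutive")
  daily <- env |>
    dplyr::filter(.data$day %in% days) |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(vpd = mean(.data$vpd_kpa),
                     par = mean(.data$par_umol_m2_s), .groups = "drop")
  starts <- seq_len(length(days) - k + 1)
  score <- vapply(starts, function(s) {
    w <- daily[s:(s + k - 1), ]
    cv2 <- function(x) if (mean(x) == 0) 0 else var(x) / mean(x)^2
    cv2(w$vpd) + cv2(w$par)
  }, numeric(1))
  best <- which.min(score)  # which.min takes the earliest on ties
  days[best:(best + k - 1)]
}

#' Extract the daily physiological trait table of one plant
#'
#' Runs the full extraction chain — irrigation events, smoothing, daily
#' transpiration, calculated plant weight, soil water content, momentary
#' transpiration, midday aggregation, canopy conductance — and returns one
#' row per day.
#'
#' @inheritParams estimate_plant_weight
#' @return Tibble (`daily_traits`): `plant_id`, `line`, `day`, `phase`,
#'   `dt_g`, `tr_midday_mmol_s`, `e_midday`, `gsc_midday`, `cpw_g`,
#'   `cpw_gain_g`, `swc_predawn`, `swc_midday`, `capacity_day`, `clipped`,
#'   `n_missing`, `flag_missing`. `e_midday` and `gsc_midday` are on the
#'   platform scale (1e-3 mmol s^-1 g^-1).
#' @export
extract_daily_traits <- function(series, const = extraction_constants(),
                                 meta = NULL, schedule = NULL) {
  meta <- .series_meta(series, meta)
  if (is.null(schedule) && inherits(series, "plant_series")) {
    schedule <- series$schedule
  }
  d <- .series_data(series)
  dt_tbl <- daily_transpiration(series, const, meta)
  cpw <- estimate_plant_weight(series, const, meta, schedule)
  # net weight decline understates transpiration by the mass the plant
  # gained while transpiring; correct with the plant's own growth efficiency
  ge_corr <- min(attr(cpw, "ge_est") %||% 0, 0.5)
  dt_tbl$dt_g <- dt_tbl$dt_g / (1 - ge_corr)
  swc <- soil_water_content(series, cpw, const, meta)
  tr <- momentary_transpiration(series, const, meta)

  window_agg <- function(sel, suffix) {
    tibble::tibble(day = tr$day[sel], tr = tr$tr_signed_mmol_s[sel],
                   vpd = d$vpd_kpa[sel], par = d$par_umol_m2_s[sel]) |>
      dplyr::group_by(.data$day) |>
      dplyr::summarise("tr_{suffix}" := pmax(0, mean(.data$tr, na.rm = TRUE)),
                       "vpd_{suffix}" := mean(.data$vpd),
                       "par_{suffix}" := mean(.data$par), .groups = "drop")
  }
  mid <- d$hour >= const$midday[1] & d$hour < const$midday[2]
  fitw <- d$hour >= const$fit_window[1] & d$hour < const$fit_window[2]
  tr_mid <- dplyr::left_join(window_agg(mid, "midday"), window_agg(fitw, "fit"),
                             by = "day") |>
    dplyr::rename(tr_midday_mmol_s = "tr_midday")
  # demand factor relative to the series' reference forcing, used to
  # normalize E across days of unequal atmospheric demand
  par_ref <- meta$par_ref %||% mean(tr_mid$par_midday)
  vpd_ref <- meta$vpd_ref %||% mean(tr_mid$vpd_midday)
  swc_sum <- swc |>
    dplyr::mutate(predawn = .data$hour >= const$predawn[1] &
                    .data$hour < const$predawn[2],
                  midday = mid, fitw = fitw) |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(
      swc_predawn = mean(.data$swc_pct[.data$predawn]),
      swc_midday = mean(.data$swc_pct[.data$midday]),
      swc_fit = mean(.data$swc_pct[.data$fitw]),
      # a day's fit point is unusable only if the midday window itself
      # is mostly clipped (noise around 100 % at pre-dawn is harmless)
      clipped = mean(.data$clipped[.data$midday]) > 0.5,
      .groups = "drop")

  out <- dt_tbl |>
    dplyr::left_join(cpw, by = "day") |>
    dplyr::left_join(tr_mid, by = "day") |>
    dplyr::left_join(swc_sum, by = "day") |>
    dplyr::mutate(
      e_midday = E_PLATFORM_SCALE * .data$tr_midday_mmol_s / .data$cpw_g,
      demand_midday = (.data$par_midday / par_ref) * (.data$vpd_midday / vpd_ref),
      e_midday_norm = .data$e_midday / .data$demand_midday,
      e_fit = E_PLATFORM_SCALE * .data$tr_fit / .data$cpw_g,
      demand_fit = (.data$par_fit / par_ref) * (.data$vpd_fit / vpd_ref),
      e_fit_norm = .data$e_fit / .data$demand_fit,
      gsc_midday = canopy_conductance(.data$e_midday, .data$vpd_midday,
                                      const$p_atm, const$vpd_floor),
      phase = if (!is.null(schedule)) phase_of_day(schedule, .data$day)
              else NA_character_,
      plant_id = meta$plant_id %||% NA_character_,
      line = meta$line %||% NA_character_
    ) |>
    dplyr::select("plant_id", "line", "day", "phase", "dt_g",
                  "tr_midday_mmol_s", "e_midday", "e_midday_norm",
                  "demand_midday", "e_fit_norm", "swc_fit", "gsc_midday",
                  "cpw_g", "cpw_gain_g", "swc_predawn", "swc_midday",
                  "capacity_day", "clipped", "n_missing", "flag_missing")
  structure(out, ge_est = attr(cpw, "ge_est"), class = c("daily_traits", class(out)))
}

#' Extract daily traits for a whole cohort
#'
#' @param cohort List of `plant_series`.
#' @param const [extraction_constants()].
#' @return Row-bound `daily_traits` tibble over all plants.
#' @export
extract_cohort_traits <- function(cohort, const = extraction_constants()) {
  out <- purrr::map_dfr(cohort, extract_daily_traits, const = const)
  class(out) <- unique(c("daily_traits", class(out)))
  out
}
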