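# Replicate-then-line aggregation: each metric is computed per plant, then
# summarized per line as mean +/- SE (matching the per-line mean +/- SE
# presentation of replicated lysimeter experiments).
.line_summary <- function(per_plant, value_col, out_col) {
  per_plant |>
    dplyr::group_by(.data$line) |>
    dplyr::summarise(
      "{out_col}" := mean(.data[[value_col]], na.rm = TRUE),
      "{out_col}_se" := {
        v <- .data[[value_col]][is.finite(.data[[value_col]])]
        if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
      },
      n = sum(is.finite(.data[[value_col]])),
      .groups = "drop"
    )
}

.window_mean <- function(daily, days, col) {
  daily |>
    dplyr::filter(.data$day %in% days, !.data$flag_missing) |>
    dplyr::group_by(.data$plant_id, .data$line) |>
    dplyr::summarise(value = mean(.data[[col]], na.rm = TRUE), .groups = "drop")
}

#' Vigor: mean daily plant-weight gain in a well-watered window
#'
#' Average calculated-plant-weight gain per day over a pre-treatment
#' reference window (days 7-11 by default), per plant, then mean +/- SE per
#' line.
#'
#' @param daily A `daily_traits` table.
#' @param window Day indices of the pre-treatment window.
#' @return Tibble: `line`, `vigor`, `vigor_se`, `n` (g day^-1).
#' @export
vigor <- function(daily, window = 7:11) {
  if (length(window) == 0) stop("empty vigor window")
  .window_mean(daily, window, "cpw_gain_g") |>
    .line_summary("value", "vigor")
}

#' Resilience: post-rewatering over pre-drought growth rate
#'
#' Ratio of the mean CPW gain rate in the rewatering window (days 51-55 by
#' default) to that in the pre-treatment window (days 7-11), computed per
#' plant then summarized per line. Plants with non-positive pre-treatment
#' gain are flagged undefined (`NA`). `basis = "level"` uses the CPW level
#' instead of the gain rate.
#'
#' @param daily A `daily_traits` table.
#' @param window_rewater,window_pre Day windows.
#' @param basis `"gain"` (default) or `"level"`.
#' @return Tibble: `line`, `resilience`, `resilience_se`, `n`.
#' @export
resilience <- function(daily, window_rewater = 51:55, window_pre = 7:11,
                       basis = c("gain", "level")) {
  basis <- match.arg(basis)
  col <- if (basis == "gain") "cpw_gain_g" else "cpw_g"
  pre <- .window_mean(daily, window_pre, col)
  rw <- .window_mean(daily, window_rewater, col)
  dplyr::inner_join(pre, rw, by = c("plant_id", "line"),
                    suffix = c("_pre", "_rw")) |>
    dplyr::mutate(ratio = ifelse(.data$value_pre > 0,
                                 .data$value_rw / .data$value_pre, NA_real_)) |>
    .line_summary("ratio", "resilience")
}

#' Recovery: rewatering over drought daily transpiration
#'
#' Ratio of mean daily transpiration in the rewatering window (days 51-54 by
#' default) to that in the drought window (days 18-26), per plant then per
#' line. Plants with zero drought transpiration are flagged undefined.
#'
#' @param daily A `daily_traits` table.
#' @param window_rewater,window_drought Day windows.
#' @return Tibble: `line`, `recovery`, `recovery_se`, `n`.
#' @export
recovery <- function(daily, window_rewater = 51:54, window_drought = 18:26) {
  rw <- .window_mean(daily, window_rewater, "dt_g")
  dr <- .window_mean(daily, window_drought, "dt_g")
  dplyr::inner_join(dr, rw, by = c("plant_id", "line"),
                    suffix = c("_dr", "_rw")) |>
    dplyr::mutate(ratio = ifelse(.data$value_dr > 0,
                                 .data$value_rw / .data$value_dr, NA_real_)) |>
    .line_summary("ratio", "recovery")
}

#' Cumulative transpiration over the experiment
#'
#' Sum of daily transpiration per plant (missing-flagged days excluded, with
#' their count reported), then mean +/- SE per line.
#'
#' @param daily A `daily_traits` table.
#' @param days Optional day subset (default: all days present).
#' @return Tibble: `line`, `cum_transpiration`, `cum_transpiration_se`, `n`,
#'   with attribute `"n_excluded"` (count of missing-flagged plant-days).
#' @export
cumulative_transpiration <- function(daily, days = NULL) {
  if (!is.null(days)) daily <- dplyr::filter(daily, .data$day %in% days)
  n_excl <- sum(daily$flag_missing, na.rm = TRUE)
  if (n_excl > 0) {
    warning(sprintf("%d missing-flagged plant-days excluded", n_excl))
  }
  per_plant <- daily |>
    dplyr::filter(!.data$flag_missing) |>
    dplyr::group_by(.data$plant_id, .data$line) |>
    dplyr::summarise(value = sum(.data$dt_g), .groups = "drop")
  structure(.line_summary(per_plant, "value", "cum_transpiration"),
            n_excluded = n_excl)
}

#' Water use efficiency
#'
#' Dry biomass produced per gram of water transpired.
#'
#' @param biomass_dry Dry biomass, g (> 0).
#' @param cum_transp Cumulative transpiration, g (> 0).
#' @return WUE in g g^-1, vectorized.
#' @examples
#' wue(60, 10000)  # 0.006
#' @export
wue <- function(biomass_dry, cum_transp) {
  if (any(!is.finite(cum_transp)) || any(cum_transp <= 0)) {
    stop("cumulative transpiration must be positive")
  }
  if (any(biomass_dry <= 0)) stop("dry biomass must be positive")
  biomass_dry / cum_transp
}

#' Harvest component summary
#'
#' Per replicate: total dry biomass as husk + seed + shoot, harvest index as
#' `100 * yield / biomass`, and thousand-grain weight as
#' `1000 * yield / seed_count` (undefined-flagged when there are no seeds).
#'
#' @param harvest Data frame with columns `plant_id`, `line`,
#'   `husk_g`, `seed_g`, `shoot_g`, `seed_count`. `seed_g` is the grain
#'   yield per replicate.
#' @return Tibble per replicate: inputs plus `biomass_dry`, `yield_g`,
#'   `harvest_index`, `tgw`.
#' @export
harvest_summary <- function(harvest) {
  stopifnot(all(c("husk_g", "seed_g", "shoot_g", "seed_count") %in%
                  names(harvest)))
  if (any(harvest$husk_g < 0 | harvest$seed_g < 0 | harvest$shoot_g < 0 |
            harvest$seed_count < 0)) {
    stop("harvest components must be non-negative")
  }
  if (any(harvest$seed_count == 0 & harvest$seed_g > 0)) {
    stop("positive yield with zero seed count")
  }
  harvest |>
    dplyr::mutate(
      biomass_dry = .data$husk_g + .data$seed_g + .data$shoot_g,
      yield_g = .data$seed_g,
      harvest_index = ifelse(.data$biomass_dry > 0,
                             100 * .data$yield_g / .data$biomass_dry, NA_real_),
      tgw = ifelse(.data$seed_count > 0,
                   1000 * .data$yield_g / .data$seed_count, NA_real_)
    )
}

#' Synthetic harvest table from simulated final plant weights
#'
#' Emulates an end-of-experiment destructive harvest for a simulated cohort:
#' dry biomass is a fixed dry-matter fraction of the final calculated plant
#' weight; grain yield follows the line's harvest-index parameter and grain
#' count its thousand-grain weight; the husk takes a fixed share of the
#' non-grain biomass. Labelled synthetic: no measured harvest data exist for
#' the simulated lines.
#'
#' @param cohort List of `plant_series`.
#' @param lines Line parameter table with `hi_pct` and `tgw_g` columns.
#' @param dry_frac Dry-matter fraction of final fresh weight.
#' @param husk_frac Husk share of non-grain dry biomass.
#' @return Tibble: `plant_id`, `line`, `husk_g`, `seed_g`, `shoot_g`,
#'   `seed_count`.
#' @export
simulate_harvest <- function(cohort, lines, dry_frac = 0.30,
                             husk_frac = 0.12) {
  purrr::map_dfr(cohort, function(s) {
    row <- lines[lines$line == s$meta$line, ]
    stopifnot(nrow(row) == 1)
    biomass <- dry_frac * tail(s$truth$plant_fw_g, 1)
    seed <- row$hi_pct / 100 * biomass
    husk <- husk_frac * (biomass - seed)
    tibble::tibble(
      plant_id = s$meta$plant_id, line = s$meta$line,
      husk_g = husk, seed_g = seed, shoot_g = biomass - seed - husk,
      seed_count = round(1000 * seed / row$tgw_g)
    )
  })
}

#' Assemble the per-line metrics table
#'
#' Combines phase-window transpiration means, vigor, resilience, recovery,
#' cumulative transpiration, WUE and harvest components into one row per
#' line.
#'
#' @param daily A `daily_traits` table for the cohort.
#' @param harvest Harvest table (see [harvest_summary()]); optional.
#' @param theta Output of [theta_by_cohort()]; optional (adds `theta_c`,
#'   `e_max`).
#' @param windows Named list of day windows: `vigor_pre`, `resilience_rewater`,
#'   `recovery_rewater`, `recovery_drought`, `dt_pre`, `dt_drought`,
#'   `dt_rewater`.
#' @return Tibble with one row per line (metric columns plus `_se` columns).
#' @export
build_metrics <- function(daily, harvest = NULL, theta = NULL,
                          windows = metric_windows()) {
  dt_phase <- function(days, name) {
    .window_mean(daily, days, "dt_g") |> .line_summary("value", name)
  }
  out <- vigor(daily, windows$vigor_pre) |>
    dplyr::left_join(
      resilience(daily, windows$resilience_rewater, windows$vigor_pre),
      by = "line", suffix = c("", ".y")) |>
    dplyr::left_join(
      recovery(daily, windows$recovery_rewater, windows$recovery_drought),
      by = "line", suffix = c("", ".y")) |>
    dplyr::left_join(dt_phase(windows$dt_pre, "dt_pre"), by = "line",
                     suffix = c("", ".y")) |>
    dplyr::left_join(dt_phase(windows$dt_drought, "dt_drought"), by = "line",
                     suffix = c("", ".y")) |>
    dplyr::left_join(dt_phase(windows$dt_rewater, "dt_rewater"), by = "line",
                     suffix = c("", ".y")) |>
    dplyr::left_join(cumulative_transpiration(daily), by = "line",
                     suffix = c("", ".y")) |>
    dplyr::select(-dplyr::ends_with(".y"))
  if (!is.null(harvest)) {
    hs <- harvest_summary(harvest) |>
      dplyr::group_by(.data$line) |>
      dplyr::summarise(
        biomass_dry = mean(.data$biomass_dry),
        yield_g = mean(.data$yield_g),
        seed_count = mean(.data$seed_count),
        harvest_index = mean(.data$harvest_index, na.rm = TRUE),
        tgw = mean(.data$tgw, na.rm = TRUE),
        .groups = "drop")
    out <- dplyr::left_join(out, hs, by = "line") |>
      dplyr::mutate(wue = wue(.data$biomass_dry, .data$cum_transpiration))
  }
  if (!is.null(theta)) {
    out <- dplyr::left_join(
      out,
      dplyr::select(theta, "line", theta_c = "theta_c", e_max = "tr_max"),
      by = "line")
  }
  out
}

#' Default metric day windows
#'
#' The day-number defaults of the 55-day replicated protocol: vigor over
#' pre-treatment days 7-11, phase transpiration means over the stable
#' windows 7-11 / 22-26 / 51-55, resilience over rewatering days 51-55,
#' recovery over rewatering days 51-54 versus drought days 18-26. All
#' overridable, e.g. from [select_stable_window()].
#'
#' @param vigor_pre,dt_pre,dt_drought,dt_rewater,resilience_rewater,recovery_rewater,recovery_drought
#'   Integer day vectors.
#' @return Named list of windows.
#' @export
metric_windows <- function(vigor_pre = 7:11,
                           dt_pre = 7:11,
                           dt_drought = 22:26,
                           dt_rewater = 51:55,
                           resilience_rewater = 51:55,
                           recovery_rewater = 51:54,
                           recovery_drought = 18:26) {
  list(vigor_pre = vigor_pre, dt_pre = dt_pre, dt_drought = dt_drought,
       dt_rewater = dt_rewater, resilience_rewater = resilience_rewater,
       recovery_rewater = recovery_rewater,
       recovery_drought = recovery_drought)
}
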