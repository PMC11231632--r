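#' Genotype ground-truth parameters for the water-balance simulator
#'
#' @param e_max_true Maximum normalized transpiration at reference forcing,
#'   platform units (1e-3 mmol s^-1 per g plant fresh weight); printed
#'   barley values sit around 8-15.
#' @param theta_c_true Stomatal-closure threshold, percent of pot-capacity
#'   soil water content (the breakpoint the pipeline should recover).
#' @param decline_slope_true Fractional loss of `e_max_true` per percentage
#'   point of SWC below the threshold (linear-plateau stomatal response).
#' @param growth_efficiency Gram of fresh plant weight gained per gram of
#'   water transpired (before logistic damping near `w_max`).
#' @param recovery_factor Fraction of pre-drought transpiration capacity
#'   restored during rewatering, in (0, 1].
#' @param strategy_label_true Optional ground-truth strategy label, one of
#'   `"dynamic"`, `"isohydric"`, `"anisohydric"`.
#' @return Object of class `genotype_params` (named list).
#' @export
genotype_params <- function(e_max_true,
                            theta_c_true,
                            decline_slope_true,
                            growth_efficiency = 0.02,
                            recovery_factor = 1,
                            strategy_label_true = NA_character_) {
  stopifnot(
    e_max_true >= 0,  # 0 permitted: degenerate no-transpiration diagnostic
    theta_c_true > 0, theta_c_true < 100,
    decline_slope_true > 0,
    growth_efficiency > 0, growth_efficiency < 1,
    recovery_factor > 0, recovery_factor <= 1
  )
  if (!is.na(strategy_label_true)) {
    strategy_label_true <- match.arg(strategy_label_true,
                                     c("dynamic", "isohydric", "anisohydric"))
  }
  structure(
    list(
      e_max_true = e_max_true,
      theta_c_true = theta_c_true,
      decline_slope_true = decline_slope_true,
      growth_efficiency = growth_efficiency,
      recovery_factor = recovery_factor,
      strategy_label_true = strategy_label_true
    ),
    class = "genotype_params"
  )
}

#' Initial pot state on the load cell
#'
#' System weight decomposes as
#' `tare + soil_dry + soil_water + plant_fresh_weight`; this identity holds
#' exactly on the simulator's noise-free trajectory.
#'
#' @param tare_weight Pot plus hardware, g.
#' @param soil_dry_weight Dry soil mass, g.
#' @param soil_water_capacity Water mass held at pot capacity, g.
#' @param soil_water Initial soil water, g; defaults to capacity (pots are
#'   mounted fully irrigated).
#' @param plant_fresh_weight Initial plant fresh weight, g.
#' @return Object of class `pot_state` (named list).
#' @export
pot_state <- function(tare_weight = 500,
                      soil_dry_weight = 1200,
                      soil_water_capacity = 1200,
                      soil_water = soil_water_capacity,
                      plant_fresh_weight = 40) {
  stopifnot(
    tare_weight >= 0, soil_dry_weight >= 0,
    soil_water_capacity > 0,
    soil_water >= 0, soil_water <= soil_water_capacity,
    plant_fresh_weight >= 0
  )
  structure(
    list(
      tare_weight = tare_weight,
      soil_dry_weight = soil_dry_weight,
      soil_water_capacity = soil_water_capacity,
      soil_water = soil_water,
      plant_fresh_weight = plant_fresh_weight
    ),
    class = "pot_state"
  )
}

#' Synthetic 18-line barley parameter panel
#'
#' A synthetic genotype panel for the replicated 55-day protocol, anchored to
#' the printed trait ranges of the European barley diversity subset it
#' emulates: normalized E_max between ~8 and ~15 platform units, closure
#' thresholds between ~26 and ~42 % SWC, and three water-use strategies.
#' Dynamic lines pair high E_max with high theta_c and shallow decline;
#' anisohydric lines pair low E_max with low theta_c and steep decline;
#' isohydric lines sit between. Named anchors: Hydrogen (E_max 15.1,
#' theta_c 42.6), Freja (E_max 8.8, theta_c 26.7). Harvest-allocation columns
#' (`hi_pct`, `tgw_g`) parameterize the synthetic harvest table; Hankkija 673
#' carries a six-row allocation (high harvest index, moderate grain weight).
#'
#' This table is simulator ground truth, not measured data.
#'
#' @return Tibble with one row per line: `line`, `strategy_true`,
#'   `e_max_true`, `theta_c_true`, `decline_slope_true`,
#'   `growth_efficiency`, `recovery_factor`, `hi_pct`, `tgw_g`.
#' @export
barley_lines_18 <- function() {
  tibble::tribble(
    ~line,          ~strategy_true, ~e_max_true, ~theta_c_true, ~decline_slope_true, ~growth_efficiency, ~recovery_factor, ~hi_pct, ~tgw_g,
    "Hydrogen",     "dynamic",      15.1,        42.6,          0.035,               0.023,              0.95,             1.8,     40,
    "Hankkija 673", "dynamic",      14.0,        40.0,          0.035,               0.020,              0.55,             16.9,    26.8,
    "Baronesse",    "dynamic",      14.5,        41.0,          0.035,               0.028,              0.95,             6.0,     42,
    "Isaria",       "dynamic",      13.5,        37.0,          0.040,               0.026,              0.85,             0.8,     35,
    "Etu",          "isohydric",    12.0,        35.0,          0.050,               0.022,              0.80,             5.0,     38,
    "Gorm",         "isohydric",    11.5,        34.0,          0.050,               0.028,              0.90,             7.0,     40,
    "Gate",         "isohydric",    11.8,        36.0,          0.045,               0.021,              0.75,             4.5,     37,
    "Frisia",       "isohydric",    11.2,        33.0,          0.050,               0.020,              0.80,             5.5,     39,
    "Barke",        "isohydric",    11.0,        32.5,          0.055,               0.023,              0.85,             6.5,     44,
    "Chanell",      "isohydric",    11.6,        34.5,          0.050,               0.030,              0.85,             8.0,     41,
    "Favorit",      "isohydric",    10.8,        32.0,          0.055,               0.019,              0.80,             5.0,     38,
    "Arvo",         "anisohydric",  10.5,        31.0,          0.065,               0.018,              0.80,             4.0,     36,
    "Herse",        "anisohydric",  9.8,         29.0,          0.075,               0.017,              0.85,             12.0,    38,
    "Formula",      "anisohydric",  9.5,         28.5,          0.075,               0.016,              0.90,             3.5,     35,
    "Artturi",      "anisohydric",  9.2,         28.0,          0.080,               0.016,              0.85,             4.0,     34,
    "Eero",         "anisohydric",  9.6,         29.5,          0.070,               0.015,              0.70,             5.6,     32,
    "Binder",       "anisohydric",  9.0,         27.5,          0.080,               0.017,              0.90,             3.0,     33,
    "Freja",        "anisohydric",  8.8,         26.7,          0.085,               0.020,              0.90,             1.0,     42
  )
}

#' Synthetic n-line diversity panel
#'
#' Deterministic synthetic panel emulating a wider diversity screening: lines
#' span the same E_max and theta_c ranges as [barley_lines_18()] with a
#' positive E_max/theta_c association (the pattern reported for the
#' population this panel emulates) plus deterministic off-diagonal scatter.
#'
#' @param n Number of lines.
#' @return Tibble with the same columns as [barley_lines_18()].
#' @export
barley_lines <- function(n = 81) {
  stopifnot(n >= 1)
  i <- seq_len(n)
  u <- (i - 0.5) / n
  # deterministic low-discrepancy scatter around the main axis
  w <- ((i * 0.6180339887) %% 1) - 0.5
  e_max <- 8.5 + 7 * u + 1.2 * w
  theta <- 26 + 16 * u - 6 * w
  slope <- 0.09 - 0.05 * u + 0.01 * w
  ge <- 0.015 + 0.015 * ((i * 0.3819660113) %% 1)
  rec <- 0.6 + 0.35 * ((i * 0.7548776662) %% 1)
  strat <- ifelse(u >= 2 / 3, "dynamic", ifelse(u < 1 / 3, "anisohydric", "isohydric"))
  tibble::tibble(
    line = sprintf("L%03d", i),
    strategy_true = strat,
    e_max_true = round(e_max, 2),
    theta_c_true = round(pmin(45, pmax(20, theta)), 2),
    decline_slope_true = round(pmax(0.03, slope), 3),
    growth_efficiency = round(ge, 4),
    recovery_factor = round(rec, 3),
    hi_pct = round(1 + 15 * ((i * 0.2360679775) %% 1), 1),
    tgw_g = round(30 + 15 * ((i * 0.5477225575) %% 1), 1)
  )
}
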