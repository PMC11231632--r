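# Construct a daily-traits table directly: metric operations are pure
# arithmetic on the table and are tested against hand-computable inputs.
make_daily <- function(lines, reps = 2, days = 1:55,
                       dt = function(day, r) 100,
                       gain = function(day, r) 10) {
  sch <- phase_schedule(11, 15, 29)
  purrr::map_dfr(lines, function(ln) {
    purrr::map_dfr(seq_len(reps), function(r) {
      tibble::tibble(
        plant_id = paste0(ln, "_", r), line = ln, day = days,
        phase = phase_of_day(sch, days),
        dt_g = dt(days, r), cpw_g = cumsum(gain(days, r)),
        cpw_gain_g = gain(days, r),
        flag_missing = FALSE, clipped = FALSE
      )
    })
  })
}

test_that("vigor equals the window mean of daily plant-weight gain", {
  d <- make_daily("A", gain = function(day, r) 10)
  v <- vigor(d)
  expect_equal(v$vigor, 10)
  expect_equal(v$n, 2)
  expect_error(vigor(d, integer(0)), "empty")
  # rising gain: mean over days 7-11
  d2 <- make_daily("A", gain = function(day, r) day)
  expect_equal(vigor(d2)$vigor, mean(7:11))
})

test_that("resilience and recovery reduce to their defining ratios", {
  d <- make_daily("A", gain = function(day, r) ifelse(day > 26, 6, 3),
                  dt = function(day, r) ifelse(day > 26, 120, 60))
  expect_equal(resilience(d)$resilience, 2)
  expect_equal(recovery(d)$recovery, 2)
  # identical rates across phases give exactly 1
  d1 <- make_daily("A")
  expect_equal(resilience(d1)$resilience, 1)
  expect_equal(recovery(d1)$recovery, 1)
})

test_that("resilience and recovery are scale invariant", {
  d <- make_daily("A", gain = function(day, r) 2 + day / 10,
                  dt = function(day, r) 50 + day)
  d2 <- dplyr::mutate(d, cpw_gain_g = cpw_gain_g * 7, dt_g = dt_g * 7)
  expect_equal(resilience(d2)$resilience, resilience(d)$resilience)
  expect_equal(recovery(d2)$recovery, recovery(d)$recovery)
})

test_that("cumulative transpiration sums days and is phase additive", {
  d <- make_daily("A", days = 1:10, dt = function(day, r) 100)
  expect_equal(cumulative_transpiration(d)$cum_transpiration, 1000)
  d2 <- make_daily("A", dt = function(day, r) day)
  tot <- cumulative_transpiration(d2)$cum_transpiration
  parts <- sapply(list(1:11, 12:26, 27:55), function(w)
    cumulative_transpiration(d2, days = w)$cum_transpiration)
  expect_equal(sum(parts), tot)
  # missing-flagged days are excluded with a warning
  d3 <- make_daily("A", days = 1:10, dt = function(day, r) 100)
  d3$flag_missing[d3$day == 5] <- TRUE
  expect_warning(ct <- cumulative_transpiration(d3), "excluded")
  expect_equal(ct$cum_transpiration, 900)
})

test_that("linear metrics commute with replicate aggregation", {
  d <- make_daily("A", reps = 3, dt = function(day, r) 50 * r,
                  gain = function(day, r) 2 * r)
  # per-replicate then mean
  v <- vigor(d)$vigor
  ct <- cumulative_transpiration(d)$cum_transpiration
  # aggregate inputs first
  d_mean <- d |>
    dplyr::group_by(line, day, phase) |>
    dplyr::summarise(dt_g = mean(dt_g), cpw_gain_g = mean(cpw_gain_g),
                     cpw_g = mean(cpw_g), flag_missing = FALSE,
                     clipped = FALSE, .groups = "drop") |>
    dplyr::mutate(plant_id = "mean")
  expect_equal(vigor(d_mean)$vigor, v)
  expect_equal(cumulative_transpiration(d_mean)$cum_transpiration, ct)
})

test_that("WUE follows its definition and rejects degenerate input", {
  expect_equal(wue(60, 10000), 0.006)
  expect_equal(wue(c(60, 30), c(10000, 10000)), c(0.006, 0.003))
  expect_error(wue(60, 0), "positive")
  expect_error(wue(0, 100), "positive")
})

test_that("harvest summary computes biomass, harvest index and TGW", {
  h <- tibble::tibble(plant_id = "p", line = "A", husk_g = 10, seed_g = 5,
                      shoot_g = 45, seed_count = 200)
  out <- harvest_summary(h)
  expect_equal(out$biomass_dry, 60)
  expect_equal(out$harvest_index, 100 * 5 / 60)
  expect_equal(out$harvest_index, 8.33, tolerance = 1e-2)
  expect_equal(out$tgw, 25)
  # six-row style yield: 10.2 g over 380.4 seeds gives TGW near 26.8 g
  h2 <- tibble::tibble(plant_id = "p", line = "B", husk_g = 6, seed_g = 10.2,
                       shoot_g = 44.1, seed_count = 380.4)
  expect_equal(harvest_summary(h2)$tgw, 1000 * 10.2 / 380.4)
  expect_equal(harvest_summary(h2)$tgw, 26.8, tolerance = 0.1)
  # zero yield: HI 0, TGW undefined
  h3 <- tibble::tibble(plant_id = "p", line = "C", husk_g = 5, seed_g = 0,
                       shoot_g = 40, seed_count = 0)
  out3 <- harvest_summary(h3)
  expect_equal(out3$harvest_index, 0)
  expect_true(is.na(out3$tgw))
  h4 <- tibble::tibble(plant_id = "p", line = "D", husk_g = 5, seed_g = 2,
                       shoot_g = 40, seed_count = 0)
  expect_error(harvest_summary(h4), "zero seed count")
})

test_that("resilience and recovery increase with the recovery factor", {
  env <- sweep_env(seed = 17)
  vals <- sapply(c(0.5, 1), function(rf) {
    gp <- genotype_params(12, 32, 0.05, growth_efficiency = 0.02,
                          recovery_factor = rf)
    s <- simulate_plant(gp, env, sweep_schedule(), pot0 = sweep_pot(),
                        noise_sd = 1, seed = 61, plant_id = "p", line = "L")
    d <- extract_daily_traits(s)
    w <- metric_windows(vigor_pre = 3:7, dt_pre = 3:7, dt_drought = 16:20,
                        dt_rewater = 25:29, resilience_rewater = 25:29,
                        recovery_rewater = 25:28, recovery_drought = 14:20)
    c(resilience(d, w$resilience_rewater, w$vigor_pre)$resilience,
      recovery(d, w$recovery_rewater, w$recovery_drought)$recovery)
  })
  expect_gt(vals[1, 2], vals[1, 1])
  expect_gt(vals[2, 2], vals[2, 1])
})

test_that("estimated WUE recovers the simulated plant's realized WUE", {
  s <- sim_sweep_plant(theta = 32, noise_sd = 1, seed = 62)
  d <- extract_daily_traits(s)
  dry_frac <- 0.30
  wue_true <- dry_frac * tail(s$truth$plant_fw_g, 1) / sum(s$truth$transp_g)
  wue_est <- wue(dry_frac * d$cpw_g[nrow(d)], sum(d$dt_g))
  expect_lt(abs(wue_est / wue_true - 1), 0.05)
})

test_that("vigor ranks follow transpiration capacity in a uniform cohort", {
  # equal growth efficiency: growth is proportional to transpiration, so
  # vigor must rank with e_max
  env <- sweep_env(seed = 19)
  lines <- tibble::tibble(
    line = c("lo", "mid", "hi"), strategy_true = "isohydric",
    e_max_true = c(9, 12, 15), theta_c_true = 30,
    decline_slope_true = 0.05, growth_efficiency = 0.02,
    recovery_factor = 1, hi_pct = 5, tgw_g = 40
  )
  co <- make_cohort(lines, reps = 2, sweep_schedule(), env, seed = 63,
                    cv = 0.02, pot0 = sweep_pot())
  daily <- extract_cohort_traits(co)
  v <- vigor(daily, window = 3:7)
  expect_equal(v$line[order(v$vigor)], c("lo", "mid", "hi"))
})
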