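test_that("momentary transpiration is zero on constant weight", {
  d <- linear_series(n = 480, step_g = 0)
  tr <- momentary_transpiration(d, meta = flat_meta())
  expect_true(all(tr$tr_mmol_s[!tr$masked] == 0))
})

test_that("a linear loss of 18.015 g over 1000 s gives 1 mmol/s", {
  # 3-min cadence: 18.015 g over 1000 s = 0.054045 g per 180 s step
  d <- linear_series(n = 480, step_g = -18.015 * 180 / 1000)
  tr <- momentary_transpiration(d, meta = flat_meta())
  interior <- !tr$masked
  expect_equal(tr$tr_mmol_s[interior],
               rep(1, sum(interior)), tolerance = 1e-10)
})

test_that("midday transpiration tracks the noise-free truth within 5 % RMS", {
  s <- sim_sweep_plant(theta = 30, noise_sd = 1, seed = 31)
  d <- extract_daily_traits(s)
  tr <- s$truth
  mid <- tr$hour >= 11 & tr$hour < 14
  true_mid <- tapply(tr$transp_g[mid] / 180 / 18.015e-3, tr$day[mid], mean)
  est <- d$tr_midday_mmol_s[match(as.integer(names(true_mid)), d$day)]
  keep <- true_mid > 0.1 * max(true_mid)
  rel <- (est[keep] - true_mid[keep]) / true_mid[keep]
  expect_lt(sqrt(mean(rel^2)), 0.05)
})

test_that("daily transpiration handles constructed series exactly", {
  const0 <- extraction_constants(evap_frac = 0)
  expect_equal(daily_transpiration(linear_series(480, 0), const0,
                                   flat_meta())$dt_g, 0)
  dt <- daily_transpiration(linear_series(480, -0.3125), const0, flat_meta())
  expect_equal(dt$dt_g, 0.3125 * 479, tolerance = 1e-9)
  expect_equal(dt$dt_g, 149.7, tolerance = 1e-3)
  # pipeline linearity: doubling all losses doubles DT exactly
  dt2 <- daily_transpiration(linear_series(480, -0.625), const0, flat_meta())
  expect_equal(dt2$dt_g, 2 * dt$dt_g, tolerance = 1e-9)
})

test_that("daily transpiration matches simulated truth within 3 %", {
  s <- sim_sweep_plant(theta = 30, noise_sd = 1, seed = 32)
  d <- extract_daily_traits(s)
  true_dt <- tapply(s$truth$transp_g, s$truth$day, sum)
  err <- abs(d$dt_g - true_dt)
  # 3 % of truth, with an absolute floor at the weighing precision
  # (3 x noise_sd) for the near-collapse drought days
  expect_true(all(err <= pmax(0.03 * true_dt, 3)))
})

test_that("integrated momentary transpiration agrees with day accounting", {
  s <- sim_sweep_plant(theta = 30, noise_sd = 0, seed = 33)
  const <- extraction_constants()
  dt <- daily_transpiration(s, const)
  tr <- momentary_transpiration(s, const)
  integ <- tapply(ifelse(is.na(tr$tr_mmol_s), 0, tr$tr_mmol_s) *
                    180 * 18.015e-3, tr$day, sum)
  keep <- dt$dt_g > 30
  rel <- abs(integ[keep] - dt$dt_g[keep]) / dt$dt_g[keep]
  expect_lt(max(rel), 0.02)
})

test_that("calculated plant weight recovers the truth", {
  # zero growth: CPW constant across capacity days
  env <- sweep_env()
  gp0 <- genotype_params(12, 35, 0.05, growth_efficiency = 1e-9)
  s0 <- simulate_plant(gp0, env, sweep_schedule(), pot0 = sweep_pot(),
                       noise_sd = 1, seed = 41)
  c0 <- estimate_plant_weight(s0)
  cap0 <- c0$cpw_g[c0$capacity_day]
  expect_lt(max(abs(cap0 - 60)), 1)
  # growing plant: pre-treatment within 3 %, drought bookkeeping within 10 %
  s <- sim_sweep_plant(theta = 30, noise_sd = 1, seed = 42)
  cp <- estimate_plant_weight(s)
  tr <- s$truth
  pd <- tr$hour >= 2 & tr$hour < 5
  true_pw <- tapply(tr$plant_fw_g[pd], tr$day[pd], mean)
  rel <- abs(cp$cpw_g - true_pw) / true_pw
  expect_lt(max(rel[1:9]), 0.03)
  expect_lt(max(rel, na.rm = TRUE), 0.10)
})

test_that("soil water content is accurate and flags the termination day", {
  s <- sim_sweep_plant(theta = 30, noise_sd = 1, seed = 43)
  d <- extract_daily_traits(s)
  tr <- s$truth
  pd <- tr$hour >= 2 & tr$hour < 5
  true_swc <- tapply(tr$swc_pct[pd], tr$day[pd], mean)
  expect_lt(max(abs(d$swc_predawn - true_swc)), 2)
  # first pre-dawn below the stop threshold equals the simulator's record
  dr_days <- phase_days(s$schedule, "drought")
  first_low <- dr_days[which(d$swc_predawn[d$day %in% dr_days] < 15)[1]]
  expect_equal(first_low, s$meta$termination_day)
  # pre-dawn after refill sits at capacity within noise
  expect_true(all(abs(d$swc_predawn[d$day <= 9] - 100) < 1))
})

test_that("SWC is non-increasing through irrigation-free daylight spans", {
  s <- sim_sweep_plant(theta = 30, noise_sd = 0, seed = 44)
  swc <- soil_water_content(s)
  day_swc <- swc$swc_pct[swc$hour >= 7 & swc$hour < 17 & swc$day == 12]
  expect_true(all(diff(day_swc) <= 1e-9))
})

test_that("canopy conductance follows its algebraic definition and floor", {
  expect_equal(canopy_conductance(1, 101.3 / 100), 100)
  expect_true(is.na(canopy_conductance(1, 0.05)))
  # recovered midday GSc is proportional to the simulator's stomatal rule
  s <- sim_sweep_plant(theta = 30, noise_sd = 1, seed = 45)
  d <- extract_daily_traits(s)
  pre <- d$phase == "pre" & d$day >= 2
  mid <- s$data$hour >= 11 & s$data$hour < 14
  vpd_mid <- tapply(s$data$vpd_kpa[mid], s$data$day[mid], mean)
  expected <- 12 * d$demand_midday[pre] * 101.3 /
    as.numeric(vpd_mid[as.character(d$day[pre])])
  expect_lt(max(abs(d$gsc_midday[pre] / expected - 1)), 0.05)
})

test_that("stable-window selection agrees with exhaustive search", {
  sch <- phase_schedule(9, 11, 9)
  env <- make_env_series(sch, seed = 8)
  days <- phase_days(sch, "drought")
  w <- select_stable_window(env, days, k = 5)
  expect_length(w, 5)
  expect_true(all(diff(w) == 1))
  # brute-force oracle over all windows
  daily <- aggregate(cbind(vpd = env$vpd_kpa, par = env$par_umol_m2_s),
                     by = list(day = env$day), FUN = mean)
  daily <- daily[daily$day %in% days, ]
  cv2 <- function(x) var(x) / mean(x)^2
  scores <- sapply(seq_len(nrow(daily) - 4), function(s) {
    w <- daily[s:(s + 4), ]
    cv2(w$vpd) + cv2(w$par)
  })
  expect_equal(w[1], days[which.min(scores)])
  # constant environment: earliest window wins the tie
  envc <- make_env_series(sch, c(25, 25), c(50, 50), 500, jitter = 0,
                          seed = 1)
  expect_equal(select_stable_window(envc, days, 5), days[1:5])
  expect_error(select_stable_window(env, days[1:3], 5), "shorter")
})

test_that("days with too many missing samples are flagged", {
  s <- sim_sweep_plant(theta = 30, noise_sd = 1, seed = 46)
  s$data$weight_g[s$data$day == 3][1:150] <- NA  # > 20 % of 480
  d <- extract_daily_traits(s)
  expect_true(d$flag_missing[d$day == 3])
  expect_false(any(d$flag_missing[d$day != 3]))
})
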