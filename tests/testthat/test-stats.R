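test_that("pearson correlation matches hand-computed values", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -2 * x + 7), -1)
  # deviations (-1.5,-0.5,.5,1.5)x(-0.5,-1.5,1.5,0.5): r = 3/sqrt(5*5)
  expect_equal(pearson_r(x, c(2, 1, 4, 3)), 0.6)
  expect_warning(r0 <- pearson_r(x, rep(2, 4)), "zero variance")
  expect_true(is.na(r0))
  expect_error(pearson_r(1:2, 1:2), "3 complete pairs")
})

test_that("clearly separated groups get distinct letters", {
  withr::local_seed(1)
  d <- data.frame(
    g = rep(c("A", "B", "C"), each = 5),
    y = rep(c(0, 10, 20), each = 5) + rnorm(15, 0, 0.01)
  )
  out <- anova_tukey_letters(d$y, d$g)
  expect_equal(sort(out$letters), c("a", "b", "c"))
  expect_lt(attr(out, "anova_p"), 1e-6)
})

test_that("identical groups share one letter", {
  d <- data.frame(g = rep(c("A", "B", "C"), each = 3), y = rep(5, 9))
  out <- anova_tukey_letters(d$y, d$g)
  expect_equal(out$letters, c("a", "a", "a"))
})

test_that("a borderline chain produces an overlapping letter pattern", {
  # exact group means 0 / 1.2 / 2.4 with pooled within-sd 1.2, n = 5:
  # the Tukey HSD at alpha 0.05 separates only the extreme pair
  withr::local_seed(2)
  resid <- replicate(3, {
    r <- rnorm(5)
    (r - mean(r)) / sd(r) * 1.2
  })
  y <- as.vector(resid) + rep(c(0, 1.2, 2.4), each = 5)
  g <- rep(c("lo", "mid", "hi"), each = 5)
  out <- anova_tukey_letters(y, g)
  sig <- tukey_decisions(y, g)
  expect_true(sig["lo", "hi"])
  expect_false(sig["lo", "mid"])
  expect_false(sig["mid", "hi"])
  expect_equal(out$letters, c("a", "ab", "b"))
})

test_that("shared letters reproduce the Tukey decision matrix exactly", {
  withr::local_seed(33)
  for (trial in 1:60) {
    k <- sample(3:6, 1)
    n <- sample(3:7, k, replace = TRUE)
    g <- rep(paste0("G", seq_len(k)), times = n)
    y <- rnorm(sum(n), mean = rep(runif(k, 0, 4), times = n))
    out <- anova_tukey_letters(y, g)
    sig <- tukey_decisions(y, g)
    ord <- out$group
    expect_identical(unname(!letters_share(out)), unname(sig[ord, ord]),
                     info = paste("trial", trial))
  }
})

test_that("groups with a single replicate are excluded with a warning", {
  y <- c(1, 2, 3, 4, 10)
  g <- c("A", "A", "B", "B", "C")
  expect_warning(out <- anova_tukey_letters(y, g), "excluded")
  expect_equal(sort(out$group), c("A", "B"))
  expect_error(suppressWarnings(anova_tukey_letters(c(1, 2), c("A", "B"))),
               "at least 2 groups")
})

test_that("strategy classification follows the rank rule", {
  m <- tibble::tibble(
    line = c("dyn1", "dyn2", "mid1", "mid2", "ani1", "ani2"),
    dt_pre = c(200, 190, 120, 110, 60, 50),
    dt_drought = c(10, 12, 50, 55, 90, 95),
    theta_c = c(42, 40, 33, 32, 27, 25)
  )
  out <- classify_strategy(m)
  expect_equal(out$strategy[out$line %in% c("dyn1", "dyn2")],
               rep("dynamic", 2))
  expect_equal(out$strategy[out$line %in% c("ani1", "ani2")],
               rep("anisohydric", 2))
  expect_equal(out$strategy[out$line %in% c("mid1", "mid2")],
               rep("isohydric", 2))
  expect_false(any(out$low_confidence))
})

test_that("degenerate and theta-free inputs classify conservatively", {
  m <- tibble::tibble(line = letters[1:5], dt_pre = 100, dt_drought = 50,
                      theta_c = 30)
  out <- classify_strategy(m)
  expect_equal(unique(out$strategy), "isohydric")
  m2 <- tibble::tibble(
    line = c("d", "m", "a"),
    dt_pre = c(200, 120, 60), dt_drought = c(10, 50, 90)
  )
  out2 <- classify_strategy(m2)
  expect_true(all(out2$low_confidence))
  expect_equal(out2$strategy, c("dynamic", "isohydric", "anisohydric"))
})

test_that("classification is permutation equivariant", {
  withr::local_seed(5)
  m <- tibble::tibble(
    line = paste0("L", 1:9),
    dt_pre = sample(50:200, 9),
    dt_drought = sample(10:100, 9),
    theta_c = runif(9, 25, 42)
  )
  out <- classify_strategy(m)
  perm <- sample(9)
  out_p <- classify_strategy(m[perm, ])
  expect_equal(out_p$strategy, out$strategy[perm])
})

test_that("rank shifts capture phase transitions", {
  m <- tibble::tibble(line = c("a", "b", "c"), dt_pre = c(3, 2, 1),
                      dt_drought = c(3, 2, 1), dt_rewater = c(3, 2, 1))
  rs <- rank_shift_table(m)
  expect_true(all(rs$shift_pre_drought == 0))
  expect_true(all(rs$shift_drought_rewater == 0))
  # perfect reversal: shift magnitudes sum to floor(n^2 / 2)
  for (n in 4:8) {
    m2 <- tibble::tibble(line = paste0("L", 1:n), dt_pre = seq_len(n),
                         dt_drought = rev(seq_len(n)),
                         dt_rewater = seq_len(n))
    rs2 <- rank_shift_table(m2)
    expect_equal(sum(abs(rs2$shift_pre_drought)), floor(n^2 / 2))
  }
})

test_that("phase correlation table covers all pairs", {
  m <- tibble::tibble(dt_pre = c(1, 2, 3, 4), dt_drought = c(4, 3, 2, 1),
                      dt_rewater = c(2, 1, 4, 3))
  pc <- phase_correlations(m)
  expect_equal(nrow(pc), 3)
  expect_equal(pc$r[pc$var_x == "dt_pre" & pc$var_y == "dt_drought"], -1)
  expect_equal(pc$r[pc$var_x == "dt_pre" & pc$var_y == "dt_rewater"], 0.6)
})

test_that("a contrast-parameterized cohort reproduces the opposing phase behavior", {
  # dynamic-type lines: high e_max, high theta (early curtailment);
  # anisohydric-type: low e_max, low theta (late curtailment); expect a
  # negative pre-vs-drought transpiration correlation across lines
  env <- sweep_env(seed = 23)
  lines <- tibble::tibble(
    line = c("dynA", "dynB", "aniA", "aniB"),
    strategy_true = c("dynamic", "dynamic", "anisohydric", "anisohydric"),
    e_max_true = c(15, 14, 9, 8.5),
    theta_c_true = c(42, 40, 27, 26),
    decline_slope_true = c(0.035, 0.035, 0.08, 0.08),
    growth_efficiency = 0.02, recovery_factor = 0.9,
    hi_pct = 5, tgw_g = 40
  )
  co <- make_cohort(lines, reps = 2, sweep_schedule(), env, seed = 71,
                    cv = 0.03, pot0 = sweep_pot())
  daily <- extract_cohort_traits(co)
  dt_pre <- .window_mean(daily, 4:8, "dt_g")
  dt_dr <- .window_mean(daily, 13:16, "dt_g")
  per_line <- dplyr::inner_join(dt_pre, dt_dr, by = c("plant_id", "line"),
                                suffix = c("_pre", "_dr")) |>
    dplyr::group_by(line) |>
    dplyr::summarise(pre = mean(value_pre), dr = mean(value_dr))
  expect_lt(pearson_r(per_line$pre, per_line$dr), -0.5)
  # dynamic lines fall in rank, anisohydric rise
  rs <- rank_shift_table(tibble::tibble(line = per_line$line,
                                        dt_pre = per_line$pre,
                                        dt_drought = per_line$dr,
                                        dt_rewater = per_line$pre))
  expect_true(all(rs$shift_pre_drought[rs$line %in% c("dynA", "dynB")] > 0))
  expect_true(all(rs$shift_pre_drought[rs$line %in% c("aniA", "aniB")] < 0))
})
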