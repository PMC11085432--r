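test_that("regime construction enforces the photoperiod and temperature window", {
  expect_s3_class(temperature_regime(27, 23), "temp_regime")
  expect_error(temperature_regime(27, 23, H_d = 14, H_n = 11), "24")
  expect_error(temperature_regime(27, 23, H_d = 0), "positive")
  expect_error(temperature_regime(50, 23), "outside")
  expect_error(temperature_regime(27, NA_real_), "finite")
})

test_that("daily ACT evaluates the day+night degree-hour differential", {
  expect_equal(daily_act(temperature_regime(27, 23, 22, 19, 14, 10)), 110)
  expect_equal(daily_act(temperature_regime(32, 24, 22, 19, 14, 10)), 190)
  # identical environments accumulate nothing
  expect_equal(daily_act(temperature_regime(22, 19, 22, 19, 14, 10)), 0)
  # cooling warmer than vegetative: clamped to zero, no negative accrual
  expect_equal(daily_act(temperature_regime(20, 18, 22, 19, 14, 10)), 0)
  # unclamped algebraic sum stays available for sensitivity checks
  expect_equal(daily_act(temperature_regime(20, 18, 22, 19, 14, 10), clamp = FALSE),
               -2 * 14 + -1 * 10)
})

test_that("day-only ACT keeps just the photoperiod term", {
  expect_equal(daily_day_act(temperature_regime(27, 23, 22, 19, 14, 10)), 70)
  expect_equal(daily_day_act(temperature_regime(32, 24, 22, 19, 14, 10)), 140)
  expect_equal(daily_day_act(temperature_regime(22, 19, 22, 19, 14, 10)), 0)
})

test_that("clamping and monotonicity hold across random regimes", {
  set.seed(11)
  for (i in 1:50) {
    reg <- random_regime()
    expect_gte(daily_act(reg), 0)
    expect_gte(daily_day_act(reg), 0)
    # raising a cooling set-point never increases accumulation
    warmer <- temperature_regime(reg$T_vd, reg$T_vn, min(45, reg$T_cd + 2),
                                 reg$T_cn, reg$H_d, reg$H_n)
    expect_lte(daily_act(warmer), daily_act(reg))
    # raising the vegetative day reference never decreases it
    hotter <- temperature_regime(min(45, reg$T_vd + 2), reg$T_vn, reg$T_cd,
                                 reg$T_cn, reg$H_d, reg$H_n)
    expect_gte(daily_act(hotter), daily_act(reg))
    # with no night differential, both indices coincide
    if (reg$T_vn <= reg$T_cn) {
      expect_equal(daily_act(reg), daily_day_act(reg))
    }
  }
})

test_that("regime accumulation is a constant-increment cumulative series", {
  reg <- phal_regime("KHM1220")
  s10 <- accumulate_regime(reg, 10)
  expect_equal(nrow(s10), 10)
  expect_equal(s10$cumulative_c_h[10], 1100)
  expect_equal(s10$cumulative_c_h, cumsum(s10$increment_c_h))
  # single-day identity
  expect_equal(accumulate_regime(reg, 1)$cumulative_c_h[1], daily_act(reg))
  # additivity: 7 days then 3 more equals 10 straight
  s7 <- accumulate_regime(reg, 7)
  s3 <- accumulate_regime(reg, 3)
  expect_equal(s7$cumulative_c_h[7] + s3$cumulative_c_h[3], s10$cumulative_c_h[10])
  # monotone nondecreasing cumulative
  expect_true(all(diff(s10$cumulative_c_h) >= 0))
  expect_error(accumulate_regime(reg, 0), "positive integer")
  # day-only index
  expect_equal(accumulate_regime(reg, 10, index = "day_only")$cumulative_c_h[10], 700)
})

test_that("high-temperature inhibition zeroes a day's accumulation when enabled", {
  hot_room <- temperature_regime(32, 24, T_cd = 28, T_cn = 19)
  expect_gt(daily_act(hot_room), 0)
  expect_equal(daily_act(hot_room, inhibition_threshold = 28), 0)
  expect_equal(daily_day_act(hot_room, inhibition_threshold = 28), 0)
  expect_equal(accumulate_regime(hot_room, 5, inhibition_threshold = 28)$cumulative_c_h[5], 0)
})

test_that("log accumulation matches regime accumulation on a square wave", {
  log <- square_wave_log(22, 19, n_days = 3)
  series <- accumulate_log(log, T_vd = 27, T_vn = 23)
  oracle <- accumulate_regime(temperature_regime(27, 23, 22, 19, 14, 10), 3)
  expect_equal(series$cumulative_c_h[3], 330)
  expect_equal(series$cumulative_c_h, oracle$cumulative_c_h, tolerance = 1e-9)
  # spec-free cross-check with a second regime/reference pair
  log2 <- square_wave_log(20, 17, n_days = 4)
  series2 <- accumulate_log(log2, T_vd = 26, T_vn = 23)
  oracle2 <- accumulate_regime(temperature_regime(26, 23, 20, 17, 14, 10), 4)
  expect_equal(series2$cumulative_c_h, oracle2$cumulative_c_h, tolerance = 1e-9)
})

test_that("a log identical to its reference accumulates nothing", {
  log <- square_wave_log(27, 23, n_days = 2)
  series <- accumulate_log(log, T_vd = 27, T_vn = 23)
  expect_true(all(series$increment_c_h == 0))
})

test_that("per-sample clamping ignores warm excursions in a log", {
  log <- square_wave_log(30, 19, n_days = 1)  # daytime warmer than reference
  series <- accumulate_log(log, T_vd = 27, T_vn = 23)
  expect_equal(series$cumulative_c_h[1], 4 * 10)  # night term only
})

test_that("gappy or disordered logs are rejected with the missing interval named", {
  t0 <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC")
  ts <- t0 + 3600 * c(0:5, 12:23)  # 6 h hole
  expect_error(temperature_log(ts, rep(20, length(ts))), "gap")
  expect_error(temperature_log(t0 + c(0, 3600, 3600), rep(20, 3)),
               "strictly increasing")
})

test_that("temperature logs round-trip through CSV", {
  log <- square_wave_log(22, 19, n_days = 1)
  path <- tempfile(fileext = ".csv")
  utils::write.csv(
    data.frame(timestamp = format(log$timestamp, "%Y-%m-%dT%H:%M:%S"),
               temp_c = log$temp_c),
    path, row.names = FALSE, quote = FALSE)
  log2 <- read_temperature_log(path)
  expect_equal(log2$temp_c, log$temp_c)
  expect_equal(accumulate_log(log2, 27, 23)$cumulative_c_h,
               accumulate_log(log, 27, 23)$cumulative_c_h)
})
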