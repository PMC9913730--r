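test_that("estimated-ST formula matches hand-evaluated cases", {
  # 38.0 + (39.0-38.0) * ((2.0-0.9)/2.0) = 38.55
  expect_equal(estimated_st(38.0, 39.0, 37.0), 38.55)
  # current value at the window max: correction annihilated
  expect_equal(estimated_st(39.0, 39.0, 37.0), 39.0)
  # degenerate window range returns the current value
  expect_equal(estimated_st(38.0, 38.0, 38.0), 38.0)
  # range below 0.9: negative coefficient pushes below the current value
  # 37.5 + 0.5 * ((0.5-0.9)/0.5) = 37.1
  expect_equal(estimated_st(37.5, 38.0, 37.5), 37.1)
})

test_that("estimated ST is equivariant under constant shifts", {
  set.seed(41)
  for (i in 1:50) {
    tem <- runif(1, 35, 40)
    mx <- tem + runif(1, 0, 3)
    mn <- tem - runif(1, 0, 3)
    shift <- runif(1, -5, 5)
    expect_equal(estimated_st(tem + shift, mx + shift, mn + shift),
                 estimated_st(tem, mx, mn) + shift)
  }
})

test_that("estimated ST respects the formula's sign structure", {
  set.seed(42)
  for (i in 1:100) {
    tem <- runif(1, 36, 40)
    mx <- tem + runif(1, 0.05, 2)
    mn <- tem - runif(1, 0.05, 2)
    est <- estimated_st(tem, mx, mn)
    if (mx - mn >= 0.9) {
      expect_true(est >= tem - 1e-12 && est <= mx + 1e-12)
    } else {
      expect_lt(est, tem)
    }
  }
})

test_that("residual subtracts the same-clock-time mean of previous days", {
  # 4 days of hourly values; same clock hour holds 38.0, 38.2, 38.4, then 39.5
  vals <- rep(38.15, 4 * 24)
  hr9 <- 9 + 1 + c(0, 24, 48, 72)  # index of 09:00 on days 1..4
  vals[hr9] <- c(38.0, 38.2, 38.4, 39.5)
  r <- residual_st(mk_hourly(vals, role = "raw_hourly_max"))
  expect_equal(value_role(r), "rst")
  got <- r$value[r$hour == t0 + (72 + 10) * 3600 - 3600]
  expect_equal(got, 39.5 - mean(c(38.0, 38.2, 38.4)))
})

test_that("residual needs min_baseline_days same-time values", {
  vals <- rep(NA_real_, 4 * 24)
  vals[1 + c(0, 72)] <- c(38.0, 38.6)     # midnight on days 1 and 4 only
  vals[2 + c(0, 24, 72)] <- c(38.0, 38.2, 38.9)  # 01:00 on days 1, 2, 4
  r <- residual_st(mk_hourly(vals, role = "raw_hourly_max"),
                   min_baseline_days = 2)
  # day-4 midnight has 1 of 3 prior values -> undefined
  expect_false((t0 + 72 * 3600) %in% r$hour)
  # day-4 01:00 has 2 of 3 -> defined
  expect_equal(r$value[r$hour == t0 + 73 * 3600], 38.9 - mean(c(38.0, 38.2)))
})

test_that("residual of any 24h-periodic series is zero where defined", {
  set.seed(17)
  for (i in 1:5) {
    day <- runif(24, 36, 40)
    vals <- rep(day, 6)
    r <- residual_st(mk_hourly(vals, role = "raw_hourly_max"))
    expect_true(nrow(r) > 0)
    expect_equal(max(abs(r$value)), 0)
  }
})

test_that("constant series is a fixed point of the full transform chain", {
  vals <- rep(38.0, 6 * 24)
  tf <- st_transforms(mk_hourly(vals, role = "raw_hourly_max"))
  expect_equal(unique(tf$estimated_st[!is.na(tf$estimated_st)]), 38.0)
  erst <- tf$estimated_rst[!is.na(tf$estimated_rst)]
  expect_true(length(erst) > 0)
  expect_equal(max(abs(erst)), 0)
})

test_that("a sustained +2 step shows up as ~+2 estimated rST against the old baseline", {
  base <- rep(37 + 0.5 * sin(2 * pi * (0:23) / 24), 8)
  vals <- base
  step_start <- 4 * 24 + 1  # start of day 5
  vals[step_start:length(vals)] <- vals[step_start:length(vals)] + 2.0
  tf <- st_transforms(mk_hourly(vals, role = "raw_hourly_max"))
  # hours of day 5 whose 3-day baseline predates the step entirely
  day5 <- tf$hour >= t0 + 4 * 86400 & tf$hour < t0 + 5 * 86400
  got <- tf$estimated_rst[day5]
  got <- got[!is.na(got)]
  expect_true(length(got) > 0)
  expect_equal(mean(got), 2.0, tolerance = 0.3)
  # pre-step hours whose baseline days all carry full windows: exactly 0
  hod <- as.numeric(tf$hour - t0, units = "hours") %% 24
  day4 <- tf$hour >= t0 + 3 * 86400 & tf$hour < t0 + 4 * 86400 & hod < 11
  expect_equal(max(abs(tf$estimated_rst[day4]), na.rm = TRUE), 0,
               tolerance = 1e-8)
})

test_that("estimated ST is undefined where window coverage is insufficient", {
  vals <- c(rep(38, 30), rep(NA_real_, 18), rep(38.5, 24))
  est <- st_estimate(mk_hourly(vals, role = "raw_hourly_max"),
                     min_coverage = 0.5)
  # hours whose trailing window holds < 12 values must be absent
  idx <- as.numeric(est$hour - t0, units = "hours")
  for (h in idx) {
    w <- vals[max(1, h - 22):(h + 1)]
    expect_gte(sum(!is.na(w)), 12)
  }
})
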