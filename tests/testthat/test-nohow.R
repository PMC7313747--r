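test_that("hourly scaling divides by the wear proportion above the threshold", {
  x <- rep(NA_real_, 60)
  x[1:5] <- 10
  res <- scale_hour(x)
  expect_true(res$valid)
  expect_equal(res$value, 600) # 50 / (5/60)
  expect_equal(res$wear_fraction, 5 / 60)

  x4 <- rep(NA_real_, 60)
  x4[1:4] <- 10
  expect_false(scale_hour(x4)$valid)
  expect_true(is.na(scale_hour(x4)$value))

  full <- rep(5, 60)
  expect_equal(scale_hour(full)$value, 300) # identity at full wear
})

test_that("daily scaling composes on scaled hourly totals", {
  h17 <- c(rep(100, 17), rep(NA_real_, 7))
  expect_false(scale_day(h17)$valid)
  h24 <- rep(100, 24)
  expect_equal(scale_day(h24)$value, 2400)
  h18 <- c(rep(500, 18), rep(NA_real_, 6))
  expect_equal(scale_day(h18)$value, 9000 / (18 / 24))
  expect_equal(scale_day(h18)$value, 12000)
})

test_that("the 14-day rule needs four valid days including a weekend day", {
  wknd <- is_weekend_14 <- rep(FALSE, 14)
  wknd[c(6, 7, 13, 14)] <- TRUE # Sat/Sun of a Monday-anchored fortnight
  d3 <- c(rep(100, 3), rep(NA_real_, 11))
  expect_false(summarize_period(d3, wknd)$valid)
  d5wk <- rep(NA_real_, 14)
  d5wk[1:5] <- 100 # five valid weekdays, no weekend day
  expect_false(summarize_period(d5wk, wknd)$valid)
  d_all <- rep(42, 14)
  res <- summarize_period(d_all, wknd)
  expect_true(res$valid)
  expect_equal(res$value, 42)
})

test_that("on complete data the scaled summaries equal plain sums exactly", {
  s <- test_participant()
  prof <- intensity_profile(s)
  for (metric in c("steps", "tdee", "light")) {
    for (lv in c("hour", "day", "period")) {
      a <- nohow_summary(s, metric, lv, profile = prof)
      b <- removal_summary(s, metric, lv, profile = prof)
      expect_equal(a$value, b$value)
      expect_true(all(a$valid))
    }
  }
})

test_that("scaled category minutes are conserved: 60 per valid hour, 1440 per valid day", {
  s <- test_participant()
  masked <- apply_plan(s, draw_plan(40, nrow(s), seed = 21))$masked
  prof <- intensity_profile(masked)
  hours <- sapply(category_names(), function(m)
    nohow_summary(masked, m, "hour", profile = prof)$value)
  hsum <- rowSums(hours)
  expect_equal(hsum[!is.na(hsum)], rep(60, sum(!is.na(hsum))),
               ignore_attr = TRUE)
  days <- sapply(category_names(), function(m)
    nohow_summary(masked, m, "day", profile = prof)$value)
  dsum <- rowSums(days)
  expect_equal(dsum[!is.na(dsum)], rep(1440, sum(!is.na(dsum))),
               ignore_attr = TRUE)
})

test_that("adding worn minutes never flips a valid unit to invalid", {
  x <- rep(NA_real_, 60)
  prev_valid <- FALSE
  for (nworn in 1:60) {
    x[nworn] <- 7
    v <- scale_hour(x)$valid
    expect_true(v >= prev_valid)
    prev_valid <- v
  }
  h <- rep(NA_real_, 24)
  prev_valid <- FALSE
  for (nh in 1:24) {
    h[nh] <- 100
    v <- scale_day(h)$valid
    expect_true(v >= prev_valid)
    prev_valid <- v
  }
})

test_that("uniform activity is recovered exactly under any valid missingness", {
  s <- flat_series(14, steps = 7, hr = 80, kcal = 1.2)
  for (seed in 1:5) {
    masked <- apply_plan(s, draw_plan(30, nrow(s), seed = seed))$masked
    day <- nohow_summary(masked, "steps", "day")
    expect_equal(day$value[day$valid], rep(7 * 1440, sum(day$valid)),
                 ignore_attr = TRUE)
    per <- nohow_summary(masked, "steps", "period")
    if (per$valid) expect_equal(per$value, 7 * 1440)
  }
})

test_that("unadjusted summaries never exceed scaled ones for accumulable metrics", {
  s <- test_participant()
  for (seed in c(4, 5)) {
    masked <- apply_plan(s, draw_plan(40, nrow(s), seed = seed))$masked
    for (metric in c("steps", "tdee")) {
      a <- nohow_summary(masked, metric, "day")
      b <- removal_summary(masked, metric, "day")
      ok <- a$valid
      expect_true(all(b$value[ok] <= a$value[ok] + 1e-9))
    }
  }
  ## definitional example: an hour half worn counts half, scaled doubles it
  x <- c(rep(10, 30), rep(NA_real_, 30))
  expect_equal(scale_hour(x)$value, 600)
  s1 <- flat_series(1, steps = 10)
  s1$steps[31:60] <- NA
  s1$heart_rate[31:60] <- NA
  s1$kcal[31:60] <- NA
  expect_equal(removal_summary(s1, "steps", "hour")$value[1], 300)
})
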