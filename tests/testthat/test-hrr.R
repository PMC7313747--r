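test_that("heart-rate anchors follow the published formulas", {
  expect_equal(max_heart_rate(40), 180)
  expect_equal(max_heart_rate(20), 194)
  expect_equal(max_heart_rate(47.46), 174.778)
  expect_error(max_heart_rate(10), "18")
  expect_equal(resting_heart_rate(50), 54)
  expect_equal(resting_heart_rate(60), 64.8)
  expect_error(resting_heart_rate(0), "positive")
})

test_that("%HRR is a linear position within the reserve", {
  prof <- intensity_profile(age = 40, hr_sleep = 60 / 1.08)
  expect_equal(prof$hr_rest, 60)
  expect_equal(percent_hrr(120, prof), 50)
  expect_equal(percent_hrr(60, prof), 0)
  expect_equal(percent_hrr(180, prof), 100)
  expect_lt(percent_hrr(50, prof), 0) # below rest is allowed
})

test_that("category cut points are half-open on the left", {
  expect_equal(as.character(classify_minute(c(19.9, 20, 39.99, 40, 59.99, 60, 95, -10))),
               c("sedentary", "light", "light", "moderate", "moderate",
                 "vigorous", "vigorous", "sedentary"))
  ## monotone in %HRR
  pct <- sort(runif(200, -20, 120))
  codes <- as.integer(classify_minute(pct))
  expect_true(all(diff(codes) >= 0))
})

test_that("sleeping heart rate equals the exhaustive window-scan oracle", {
  set.seed(31)
  ## two days with irregular night HR and scattered movement/missingness
  n <- 2 * 1440
  hr <- rnorm(n, 70, 8)
  steps <- rpois(n, 2)
  hr <- pmin(pmax(hr, 30), 200)
  s <- make_series(steps, hr)
  s$heart_rate[sample(n, 150)] <- NA
  expect_equal(sleeping_heart_rate(s), sleeping_hr_oracle(s))
})

test_that("sleeping heart rate handles constants and refuses restless nights", {
  s <- flat_series(1, steps = 0, hr = 50)
  expect_equal(sleeping_heart_rate(s), 50)
  ## a single engineered low window wins over all others
  hr <- rep(60, 1440)
  hr[101:120] <- 48
  s2 <- make_series(rep(0, 1440), hr)
  expect_equal(sleeping_heart_rate(s2), 48)
  ## steps >= 5 every minute: no qualifying window
  s3 <- flat_series(1, steps = 6, hr = 60)
  expect_error(sleeping_heart_rate(s3), "no qualifying sleep window")
})

test_that("every worn minute falls in exactly one category per day", {
  s <- test_participant()
  prof <- intensity_profile(s)
  counts <- minutes_by_category(s, prof)
  expect_equal(rowSums(counts[, category_names()]), rep(1440, 14),
               ignore_attr = TRUE)
  ## 100 missing minutes on day 1 leave 1340 classified minutes
  s$heart_rate[201:300] <- NA
  counts2 <- minutes_by_category(s, prof)
  expect_equal(sum(counts2[1, category_names()]), 1340)
  ## hr equal to rest is sedentary everywhere
  s4 <- flat_series(1, steps = 0, hr = 54)
  prof4 <- intensity_profile(age = 40, hr_sleep = 50)
  c4 <- minutes_by_category(s4, prof4)
  expect_equal(c4$sedentary, 1440)
})
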