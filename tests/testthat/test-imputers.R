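masked_fixture <- function(seed = 7) {
  s <- test_participant()
  apply_plan(s, draw_plan(40, nrow(s), seed = seed))$masked
}

test_that("mean imputation fills with the scope mean and nothing else", {
  s <- flat_series(1, steps = 7, hr = 80)
  s$steps[100:110] <- NA
  s$heart_rate[100:110] <- NA
  s$kcal[100:110] <- NA
  out <- completed_series(impute_mean(s, "individual"))
  expect_equal(out$steps[100:110], rep(7, 11))
  expect_false(anyNA(out$heart_rate))

  ## complete series is unchanged
  c0 <- flat_series(1)
  expect_identical(as.data.frame(completed_series(impute_mean(c0, "individual"))),
                   as.data.frame(c0))

  ## overall vs individual differ when the cohort mean differs
  other <- flat_series(1, steps = 100, hr = 90, id = "T2")
  ov <- completed_series(impute_mean(s, "overall", cohort = list(s, other)))
  expect_gt(ov$steps[100], 7)
  expect_error(impute_mean(make_series(c(NA, NA), c(NA, NA)), "individual"),
               "no observed")
})

test_that("PMM copies observed donors and honours m and the seed", {
  m <- masked_fixture()
  res <- impute_multiple_pmm(m, "individual", seed = 3)
  expect_equal(res$m_datasets, 7) # individual default
  mis <- is.na(m$steps)
  donors <- m$steps[!mis]
  for (j in 1:7) {
    filled <- completed_series(res, j)$steps[mis]
    expect_true(all(filled %in% donors))
  }
  res2 <- impute_multiple_pmm(m, "individual", seed = 3)
  expect_identical(lapply(res$completions, as.data.frame),
                   lapply(res2$completions, as.data.frame))
  expect_error(impute_multiple_pmm(m, "individual", m = 0, seed = 1), "m must")

  ## complete series: m identical copies
  c0 <- test_participant()
  rc <- impute_multiple_pmm(c0, "individual", m = 2, seed = 5)
  expect_identical(as.data.frame(completed_series(rc, 1)), as.data.frame(c0))
  expect_identical(as.data.frame(completed_series(rc, 2)), as.data.frame(c0))
})

test_that("overall-scope PMM defaults to 5 imputations over pooled donors", {
  m1 <- masked_fixture(11)
  m2 <- masked_fixture(12)
  attr(m2, "participant_id") <- "P43"
  res <- impute_multiple_pmm(list(P42 = m1, P43 = m2), "overall", seed = 6)
  expect_length(res, 2)
  expect_equal(res[[1]]$m_datasets, 5)
  mis <- is.na(m1$heart_rate)
  pooled <- c(m1$heart_rate[!mis], m2$heart_rate[!is.na(m2$heart_rate)])
  expect_true(all(completed_series(res[[1]])$heart_rate[mis] %in% pooled))
})

test_that("Kalman smoothing fills constants exactly and matches exact inference on a ramp", {
  ## constant channel with interior gaps
  s <- flat_series(1, steps = 4, hr = 72)
  s$steps[300:420] <- NA
  s$heart_rate[300:420] <- NA
  s$kcal[300:420] <- NA
  out <- completed_series(impute_kalman(s))
  expect_equal(out$steps[300:420], rep(4, 121), tolerance = 1e-6)
  expect_equal(out$heart_rate[300:420], rep(72, 121), tolerance = 1e-6)

  ## complete series unchanged
  c0 <- test_participant()
  expect_identical(as.data.frame(completed_series(impute_kalman(c0))),
                   as.data.frame(c0))

  ## noiseless ramp: fill agrees with direct Gaussian conditioning at the
  ## fitted (q, r) and with the underlying line
  n <- 300
  hr <- 60 + 0.1 * (1:n)
  rs <- make_series(rep(1, n), hr)
  gap <- 150:159
  rs$heart_rate[gap] <- NA
  res <- impute_kalman(rs, channels = "heart_rate")
  fill <- completed_series(res)$heart_rate[gap]
  fit <- res$details$fits$heart_rate
  q <- fit[["level"]]
  r <- fit[["epsilon"]]
  tt <- 1:n
  K <- 1e9 * (q + r + 1) + q * outer(tt, tt, pmin)
  Sy <- K + diag(r, n)
  obs <- setdiff(tt, gap)
  oracle <- as.numeric(K[gap, obs] %*% solve(Sy[obs, obs], rs$heart_rate[obs]))
  expect_equal(fill, oracle, tolerance = 1e-4)
  expect_equal(fill, 60 + 0.1 * gap, tolerance = 1e-3)

  ## too little data is refused
  tiny <- make_series(rep(1, 30), c(rep(80, 5), rep(NA, 25)))
  expect_error(impute_kalman(tiny, channels = "heart_rate"), ">= 10")
})

test_that("random forest imputation stays in the observed range and is seeded", {
  m <- masked_fixture()
  res <- impute_random_forest(m, n_trees = 10, max_iter = 2, seed = 4)
  out <- completed_series(res)
  for (ch in c("steps", "heart_rate", "kcal")) {
    mis <- is.na(m[[ch]])
    expect_true(all(out[[ch]][mis] >= min(m[[ch]], na.rm = TRUE) - 1e-9))
    expect_true(all(out[[ch]][mis] <= max(m[[ch]], na.rm = TRUE) + 1e-9))
  }
  res2 <- impute_random_forest(m, n_trees = 10, max_iter = 2, seed = 4)
  expect_identical(as.data.frame(completed_series(res2)), as.data.frame(out))
  c0 <- flat_series(1)
  expect_identical(as.data.frame(completed_series(
    impute_random_forest(c0, n_trees = 5, seed = 1))), as.data.frame(c0))
})

test_that("no imputation method alters an observed minute", {
  m <- masked_fixture(9)
  obs <- !is.na(m$heart_rate)
  results <- list(
    impute_mean(m, "individual"),
    impute_mean(m, "overall", cohort = list(m)),
    impute_multiple_pmm(m, "individual", m = 2, seed = 2),
    impute_kalman(m),
    impute_random_forest(m, n_trees = 5, max_iter = 1, seed = 2)
  )
  for (res in results) {
    for (comp in res$completions) {
      expect_identical(comp$steps[obs], m$steps[obs])
      expect_identical(comp$heart_rate[obs], m$heart_rate[obs])
      expect_identical(comp$kcal[obs], m$kcal[obs])
      expect_false(anyNA(comp$steps))
      expect_true(all(comp$steps >= 0))
      expect_true(all(comp$heart_rate > 25 & comp$heart_rate < 250))
    }
  }
})
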