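test_that("rmse matches direct recomputation", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  expect_equal(rmse(1, 4), 3)
  set.seed(2)
  a <- rnorm(50)
  b <- rnorm(50)
  expect_equal(rmse(a, b), sqrt(sum((a - b)^2) / 50))
  expect_error(rmse(1:3, 1:4), "paired")
})

test_that("equivalence verdicts coincide with 90% CI containment", {
  ## degenerate zero-variance differences
  tr <- rep(100, 10)
  eq0 <- equivalence_test(tr, tr)
  expect_true(eq0$equivalent)
  expect_equal(eq0$p_lower, 0)
  expect_equal(eq0$p_upper, 0)
  ## mean difference far above the bound with tiny spread
  set.seed(4)
  imp <- tr + 50 + rnorm(10, 0, 0.01)
  eq1 <- equivalence_test(imp, tr)
  expect_false(eq1$equivalent)
  expect_gt(eq1$p_upper, 0.99)
  expect_lt(eq1$p_lower, 0.01)
  ## CI-containment oracle on 1000 random paired fixtures
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(3:25, 1)
    true <- rnorm(n, 100, 10)
    imputed <- true + rnorm(n, runif(1, -15, 15), runif(1, 0.5, 10))
    eq <- equivalence_test(imputed, true)
    d <- imputed - true
    ci <- mean(d) + c(-1, 1) * qt(0.95, n - 1) * sd(d) / sqrt(n)
    bound <- 0.10 * mean(true)
    expect_identical(eq$equivalent, ci[1] > -bound && ci[2] < bound)
  }
  expect_error(equivalence_test(1, 1), "n >= 2")
})

test_that("agreement ICC matches a brute-force ANOVA oracle", {
  tr <- rnorm(20, 50, 8)
  expect_equal(icc_agreement(cbind(tr, tr))$icc, 1)
  set.seed(12)
  noise <- cbind(rnorm(1000), rnorm(1000))
  expect_lt(abs(icc_agreement(noise)$icc), 0.1)
  ## oracle: two-way ANOVA mean squares computed with aov()
  set.seed(5)
  for (i in 1:20) {
    nk <- c(sample(4:8, 1), sample(2:4, 1))
    ratings <- matrix(sample.int(20, prod(nk), replace = TRUE), nk[1], nk[2])
    if (var(as.numeric(ratings)) == 0) next
    df <- data.frame(y = as.numeric(ratings),
                     subj = factor(rep(seq_len(nk[1]), nk[2])),
                     rater = factor(rep(seq_len(nk[2]), each = nk[1])))
    ms <- summary(aov(y ~ subj + rater, df))[[1]][["Mean Sq"]]
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    oracle <- (msr - mse) /
      (msr + (nk[2] - 1) * mse + (nk[2] / nk[1]) * (msc - mse))
    expect_equal(icc_agreement(ratings)$icc, oracle, tolerance = 1e-10)
  }
  expect_error(icc_agreement(matrix(3, 4, 2)), "zero total variance")
})

test_that("autocorrelation profiles behave at the canonical limits", {
  set.seed(8)
  wn <- make_series(rpois(20160, 5), rnorm(20160, 80, 5))
  prof <- acf_profile(wn, "heart_rate", max_lag = 300)
  expect_equal(prof$acf[1], 1) # lag 0
  expect_true(all(abs(prof$acf[-1]) < 0.05))
  ## deterministic daily cycle peaks again at lag 1440
  cyc <- make_series(rep(0, 14 * 1440),
                     80 + 20 * sin(2 * pi * (1:(14 * 1440)) / 1440))
  pc <- acf_profile(cyc, "heart_rate", max_lag = 1500)
  ## the sample ACF tapers by (n - k)/n, so a pure cycle peaks near 0.93
  expect_gt(pc$acf[1441], 0.9)
  wn$heart_rate[5] <- NA
  expect_error(acf_profile(wn, "heart_rate"), "complete")
})

test_that("wear-requirement curves start at perfect agreement and degrade", {
  set.seed(14)
  cohort <- list(test_participant(), generate_participant(
    participant_profile(target_daily_steps = 6000), seed = 3,
    participant_id = "P3"))
  cv <- wear_requirement_curve(cohort, "hour", seed = 2)
  expect_equal(cv$icc[cv$n_deleted == 0], 1)
  ## monotone trend: late-curve agreement is below early-curve agreement
  expect_lt(mean(cv$icc[cv$n_deleted >= 45]), mean(cv$icc[cv$n_deleted <= 10]))
  expect_true(attr(cv, "requirement") >= 1)
  expect_equal(nrow(cv), 56)

  ## uniform within-hour activity makes hourly scaling exact at any deletion
  hourly_rate <- rep(rep(c(0, 2, 5, 9, 14, 3), each = 60), 14 * 4)
  u <- make_series(hourly_rate, rep(80, length(hourly_rate)))
  cu <- wear_requirement_curve(list(u), "hour", seed = 4)
  expect_true(all(cu$icc > 0.999))

  cd <- wear_requirement_curve(cohort, "day", seed = 5)
  expect_equal(cd$icc[cd$n_deleted == 0], 1)
  cp <- wear_requirement_curve(cohort, "period", seed = 6)
  expect_equal(cp$icc[cp$n_deleted == 0], 1)
})

test_that("study-1 driver has the advertised shape and a clean no-missingness limit", {
  cohort <- generate_cohort(cohort_config(2, seed = 21))
  res <- run_study1(cohort, methods = c("removal", "nohow", "individual_mean"),
                    metrics = c("steps", "light"), n_periods = 0, seed = 1)
  expect_equal(nrow(res), 3 * 2 * 3)
  expect_true(all(res$rmse == 0))
  res2 <- run_study1(cohort, methods = c("removal", "nohow"),
                     metrics = c("steps", "tdee"), n_periods = 40, seed = 2)
  rem <- subset(res2, method == "removal")
  expect_true(all(rem$mean_difference <= 0))
  expect_true(all(subset(res2, level == "period")$n <= 2))
})

test_that("study-2 driver is reproducible and tracks the missingness windows", {
  cohort <- generate_cohort(cohort_config(2, seed = 22))
  a <- run_study2(cohort, methods = "nohow", metrics = "steps",
                  windows = c(1, 10), sims_per_window = 2, seed = 3)
  b <- run_study2(cohort, methods = "nohow", metrics = "steps",
                  windows = c(1, 10), sims_per_window = 2, seed = 3)
  expect_identical(a$summary, b$summary)
  expect_equal(nrow(a$summary), 2 * 2)
  w1 <- subset(a$summary, window == 1)
  w10 <- subset(a$summary, window == 10)
  expect_lt(mean(w1$inserted_fraction), mean(w10$inserted_fraction))
})
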