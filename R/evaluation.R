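#' Root mean squared error
#'
#' @param predicted,true Paired numeric vectors of equal length (n >= 1).
#' @return `sqrt(mean((predicted - true)^2))` in the metric's units.
#' @export
rmse <- function(predicted, true) {
  if (length(predicted) != length(true) || length(true) < 1L) {
    stop("predicted and true must be paired, non-empty vectors")
  }
  sqrt(mean((predicted - true)^2))
}

#' Equivalence margin
#'
#' @param true Criterion values (or their mean).
#' @param margin_fraction Margin as a fraction of the criterion mean
#'   (default 0.10).
#' @return The half-width of the equivalence region:
#'   `margin_fraction * mean(true)`.
#' @export
equivalence_bound <- function(true, margin_fraction = 0.10) {
  margin_fraction * mean(true)
}

#' Paired TOST equivalence test
#'
#' Two one-sided paired t-tests of the difference `d = imputed - true`
#' against the margin `+/- margin_fraction * mean(true)`: `p_lower` tests
#' H0: mean d <= -bound, `p_upper` tests H0: mean d >= +bound. Equivalence is
#' declared when both are rejected at `alpha`, which is the same criterion as
#' the 90% confidence interval of the difference lying inside the margin.
#' When the differences have zero variance the verdict is
#' `|mean d| < bound`, with degenerate p-values of 0 (satisfied side) or 1.
#'
#' @param imputed,true Paired per-unit summaries (n >= 2).
#' @param margin_fraction Equivalence margin fraction (default 0.10).
#' @param alpha One-sided test level (default 0.05; equivalently a 90% CI).
#' @return List with `n`, `mean_true`, `mean_imputed`, `mean_difference`,
#'   `equivalence_bound`, `ci90` (two-sided 90% CI of the mean difference),
#'   `p_lower`, `p_upper` and `equivalent`.
#' @export
equivalence_test <- function(imputed, true, margin_fraction = 0.10,
                             alpha = 0.05) {
  n <- length(true)
  if (length(imputed) != n || n < 2L) {
    stop("paired samples with n >= 2 are required")
  }
  d <- imputed - true
  bound <- equivalence_bound(true, margin_fraction)
  md <- mean(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    p_lower <- as.numeric(md <= -bound)
    p_upper <- as.numeric(md >= bound)
    ci <- c(md, md)
  } else {
    se <- sdd / sqrt(n)
    p_lower <- stats::pt((md + bound) / se, n - 1L, lower.tail = FALSE)
    p_upper <- stats::pt((md - bound) / se, n - 1L, lower.tail = TRUE)
    ci <- md + c(-1, 1) * stats::qt(1 - alpha, n - 1L) * se
  }
  list(n = n, mean_true = mean(true), mean_imputed = mean(imputed),
       mean_difference = md, equivalence_bound = bound, ci90 = ci,
       p_lower = p_lower, p_upper = p_upper,
       equivalent = max(p_lower, p_upper) < alpha)
}

#' Two-way agreement intraclass correlation (single measure)
#'
#' ICC from the two-way (subjects x raters) ANOVA decomposition, absolute
#' agreement, single measure:
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`, with MSR, MSC and
#' MSE the mean squares for rows (subjects), columns (raters) and residual.
#'
#' @param ratings Numeric matrix, `n` subjects x `k` raters, complete.
#' @return List with `icc`, `n_subjects`, `k_raters` and the three mean
#'   squares.
#' @export
icc_agreement <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 raters")
  if (anyNA(ratings)) stop("ratings must be complete")
  grand <- mean(ratings)
  sst <- sum((ratings - grand)^2)
  if (sst < 1e-12) stop("zero total variance: ICC undefined")
  ssr <- k * sum((rowMeans(ratings) - grand)^2)
  ssc <- n * sum((colMeans(ratings) - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1L)
  msc <- ssc / (k - 1L)
  mse <- sse / ((n - 1L) * (k - 1L))
  icc <- (msr - mse) / (msr + (k - 1L) * mse + (k / n) * (msc - mse))
  list(icc = icc, n_subjects = n, k_raters = k,
       ms = c(MSR = msr, MSC = msc, MSE = mse))
}

#' Autocorrelation profile of a channel
#'
#' Sample autocorrelation at lags 0..`max_lag` for one participant's complete
#' channel.
#'
#' @param series A `participant_series` whose `channel` has no missing values.
#' @param channel `"steps"` or `"heart_rate"`.
#' @param max_lag Maximum lag in minutes (default 10080 = 7 days).
#' @return Data frame with columns `lag` and `acf` (lag 0 is 1 by definition).
#' @export
acf_profile <- function(series, channel = c("steps", "heart_rate"),
                        max_lag = 10080L) {
  channel <- match.arg(channel)
  x <- series[[channel]]
  if (anyNA(x)) stop("channel must be complete for autocorrelation")
  a <- stats::acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)
  data.frame(lag = 0:max_lag, acf = as.numeric(a$acf))
}

#' Cohort autocorrelation summary
#'
#' Per-lag mean and SD of [acf_profile()] across participants.
#'
#' @param cohort List of `participant_series`.
#' @inheritParams acf_profile
#' @return Data frame with columns `lag`, `mean`, `sd`.
#' @export
acf_cohort <- function(cohort, channel = c("steps", "heart_rate"),
                       max_lag = 10080L) {
  channel <- match.arg(channel)
  mat <- vapply(cohort, function(s) acf_profile(s, channel, max_lag)$acf,
                numeric(max_lag + 1L))
  data.frame(lag = 0:max_lag, mean = rowMeans(mat),
             sd = apply(mat, 1L, stats::sd))
}

#' Minimum wear-time requirement curves
#'
#' Deletes data incrementally and at random from a complete cohort's step
#' counts and reports the agreement ICC between the reduced and true values at
#' each increment. At the hour level, `w = 1..55` random minutes are deleted
#' per hour and the remainder is scaled by wear proportion; at the day level
#' whole hours are deleted with no scaling; at the period level whole days are
#' deleted and the mean of the remainder is compared with the true 14-day
#' mean.
#'
#' @param cohort List of complete `participant_series`.
#' @param level `"hour"`, `"day"` or `"period"`.
#' @param seed Integer seed; required.
#' @param icc_threshold Agreement threshold defining the requirement
#'   (default 0.9).
#' @return Data frame with columns `n_deleted`, `n_retained` and `icc`; the
#'   smallest retained amount with `icc >= icc_threshold` is attached as
#'   attribute `"requirement"`.
#' @export
wear_requirement_curve <- function(cohort, level = c("hour", "day", "period"),
                                   seed, icc_threshold = 0.9) {
  level <- match.arg(level)
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  set.seed(seed)
  if (level == "hour") {
    ## minutes matrix: 60 rows x (participant-hours) columns
    mats <- lapply(cohort, function(s) matrix(s$steps, nrow = 60L))
    mm <- do.call(cbind, mats)
    true <- colSums(mm)
    dels <- 0:55
    icc <- vapply(dels, function(w) {
      red <- apply(mm, 2L, function(col) {
        keep <- sample.int(60L, 60L - w)
        sum(col[keep]) / ((60 - w) / 60)
      })
      icc_agreement(cbind(true, red))$icc
    }, 0)
    unit <- 60L
  } else if (level == "day") {
    mats <- lapply(cohort, function(s) {
      hourly <- colSums(matrix(s$steps, nrow = 60L))
      matrix(hourly, nrow = 24L)
    })
    mm <- do.call(cbind, mats)
    true <- colSums(mm)
    dels <- 0:23
    icc <- vapply(dels, function(w) {
      red <- apply(mm, 2L, function(col) sum(col[sample.int(24L, 24L - w)]))
      icc_agreement(cbind(true, red))$icc
    }, 0)
    unit <- 24L
  } else {
    daily <- vapply(cohort, function(s) {
      as.numeric(rowsum(ifelse(detect_nonwear(s), s$steps, 0),
                        minute_date(s)))
    }, numeric(14L))
    true <- colMeans(daily)
    dels <- 0:13
    icc <- vapply(dels, function(w) {
      red <- apply(daily, 2L, function(col) mean(col[sample.int(14L, 14L - w)]))
      icc_agreement(cbind(true, red))$icc
    }, 0)
    unit <- 14L
  }
  out <- data.frame(n_deleted = dels, n_retained = unit - dels, icc = icc)
  meets <- out$n_retained[out$icc >= icc_threshold]
  attr(out, "requirement") <- if (length(meets)) min(meets) else NA_integer_
  out
}

## ---------------------------------------------------------------------------
## simulation-study drivers

STUDY1_METHODS <- c("removal", "overall_mean", "individual_mean", "overall_mi",
                    "individual_mi", "random_forest", "kalman", "nohow")

## deterministic sub-stream seeds below 2^31
derive_seed <- function(seed, ...) {
  s <- as.double(seed) %% 2147483647
  for (k in c(...)) s <- (s * 48271 + k + 1) %% 2147483647
  as.integer(s %% 2147483646) + 1L
}

## all-level summaries for every metric in one pass over the series.
## method "plain" = unscreened sums (used for truth and completed datasets),
## "nohow" = scaled with validity screening.
## returns list(metric -> list(hour/day/period -> list(value, valid)))
summarize_all <- function(series, method = c("plain", "nohow"), metrics,
                          profile = NULL) {
  method <- match.arg(method)
  if (any(metrics %in% category_names()) && is.null(profile)) {
    profile <- intensity_profile(series)
  }
  date <- minute_date(series)
  hour <- minute_hour(series)
  key <- paste(date, sprintf("%02d", hour))
  key <- factor(key, levels = unique(key))
  hdate <- as.Date(substr(levels(key), 1L, 10L))
  out <- list()
  for (metric in metrics) {
    v <- minute_values(series, metric, profile)
    worn <- !is.na(v)
    nw <- as.integer(rowsum(as.numeric(worn), key))
    tot <- as.numeric(rowsum(ifelse(worn, v, 0), key))
    if (method == "plain") {
      hvalue <- tot
      hvalid <- rep(TRUE, length(tot))
    } else {
      hvalid <- nw >= 5L
      hvalue <- ifelse(hvalid, tot / (nw / 60), NA_real_)
    }
    dd <- unique(hdate)
    if (method == "plain") {
      dvalue <- as.numeric(rowsum(hvalue, hdate))
      dvalid <- rep(TRUE, length(dvalue))
      pvalue <- mean(dvalue)
      pvalid <- TRUE
    } else {
      nv <- as.integer(rowsum(as.numeric(hvalid), hdate))
      dsum <- as.numeric(rowsum(ifelse(hvalid, hvalue, 0), hdate))
      dvalid <- nv >= 18L
      dvalue <- ifelse(dvalid, dsum / (nv / 24), NA_real_)
      per <- summarize_period(dvalue, is_weekend(dd))
      pvalue <- per$value
      pvalid <- per$valid
    }
    out[[metric]] <- list(
      hour = list(value = hvalue, valid = hvalid),
      day = list(value = dvalue, valid = dvalid),
      period = list(value = pvalue, valid = pvalid)
    )
  }
  out
}

## mean of m completed-dataset summaries (value-wise); validity intersected
average_summaries <- function(lst) {
  out <- lst[[1L]]
  if (length(lst) == 1L) return(out)
  for (metric in names(out)) {
    for (lv in names(out[[metric]])) {
      vals <- sapply(lst, function(s) s[[metric]][[lv]]$value)
      out[[metric]][[lv]]$value <-
        if (is.matrix(vals)) rowMeans(vals) else mean(vals)
    }
  }
  out
}

## summaries for one method applied to one masked participant
method_summaries <- function(method, masked, masked_cohort, metrics, seed,
                             mi_m_overall, mi_m_individual, mi_k,
                             rf_trees, rf_max_iter, overall_mi_cache = NULL) {
  pid <- series_id(masked)
  comp <- switch(
    method,
    removal = NULL,
    nohow = NULL,
    overall_mean = impute_mean(masked, "overall", cohort = masked_cohort),
    individual_mean = impute_mean(masked, "individual"),
    individual_mi = impute_multiple_pmm(masked, "individual",
                                        m = mi_m_individual, k = mi_k,
                                        seed = seed),
    overall_mi = if (!is.null(overall_mi_cache)) overall_mi_cache[[pid]]
                 else impute_multiple_pmm(masked, "overall", m = mi_m_overall,
                                          cohort = masked_cohort, k = mi_k,
                                          seed = seed),
    random_forest = impute_random_forest(masked, n_trees = rf_trees,
                                         max_iter = rf_max_iter, seed = seed),
    kalman = impute_kalman(masked),
    stop("unknown method: ", method)
  )
  if (method == "removal") {
    summarize_all(masked, "plain", metrics)
  } else if (method == "nohow") {
    summarize_all(masked, "nohow", metrics)
  } else {
    average_summaries(lapply(comp$completions, summarize_all,
                             method = "plain", metrics = metrics))
  }
}

#' Simulation study 1: fixed missingness, all methods
#'
#' Inserts one drawn gap plan (default 40 periods of 1-120 minutes) into each
#' participant's complete series, runs every requested method on the same
#' masked data, and compares hourly, daily and 14-day summaries of all
#' requested metrics against the held-back truth. Hourly and daily errors pool
#' all participant-hours and participant-days; period errors pool
#' participants. Units the scaling algorithm marks invalid are excluded
#' pairwise for that method.
#'
#' @param cohort List of complete 14-day `participant_series`.
#' @param methods Subset of
#'   `c("removal", "overall_mean", "individual_mean", "overall_mi",
#'   "individual_mi", "random_forest", "kalman", "nohow")`.
#' @param metrics Subset of [metric_names()].
#' @param n_periods Inserted gaps per participant (default 40).
#' @param seed Integer root seed; required.
#' @param mi_m_overall,mi_m_individual Imputation counts for the two multiple
#'   imputation scopes (defaults 5 and 7).
#' @param mi_k PMM donor pool size (default 5).
#' @param rf_trees,rf_max_iter Random forest size and iteration cap.
#' @return Data frame with one row per method x metric x level: `n`, `rmse`,
#'   `mean_true`, `mean_imputed`, `mean_difference`, `equivalence_bound`,
#'   `p_lower`, `p_upper`, `equivalent`. The mean inserted missing fraction is
#'   attached as attribute `"inserted_fraction"`.
#' @export
run_study1 <- function(cohort, methods = STUDY1_METHODS,
                       metrics = metric_names(), n_periods = 40L, seed,
                       mi_m_overall = 5L, mi_m_individual = 7L, mi_k = 5L,
                       rf_trees = 100L, rf_max_iter = 5L) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  methods <- match.arg(methods, STUDY1_METHODS, several.ok = TRUE)
  metrics <- match.arg(metrics, metric_names(), several.ok = TRUE)
  np <- length(cohort)
  masked_cohort <- vector("list", np)
  ins_frac <- numeric(np)
  for (i in seq_len(np)) {
    plan <- draw_plan(n_periods, nrow(cohort[[i]]), 120L,
                      seed = derive_seed(seed, 1L, i))
    ap <- apply_plan(cohort[[i]], plan)
    masked_cohort[[i]] <- ap$masked
    ins_frac[i] <- mean(ap$inserted)
  }
  names(masked_cohort) <- vapply(cohort, series_id, "")
  true_sum <- lapply(cohort, summarize_all, method = "plain",
                     metrics = metrics)
  overall_mi_cache <- NULL
  if ("overall_mi" %in% methods) {
    overall_mi_cache <- impute_multiple_pmm(masked_cohort, "overall",
                                            m = mi_m_overall, k = mi_k,
                                            seed = derive_seed(seed, 2L))
  }
  rows <- list()
  for (method in methods) {
    msum <- lapply(seq_len(np), function(i) {
      method_summaries(method, masked_cohort[[i]], masked_cohort, metrics,
                       seed = derive_seed(seed, 3L, i, match(method, STUDY1_METHODS)),
                       mi_m_overall, mi_m_individual, mi_k,
                       rf_trees, rf_max_iter, overall_mi_cache)
    })
    for (metric in metrics) {
      for (lv in c("hour", "day", "period")) {
        tv <- unlist(lapply(true_sum, function(s) s[[metric]][[lv]]$value))
        iv <- unlist(lapply(msum, function(s) s[[metric]][[lv]]$value))
        ok <- unlist(lapply(msum, function(s) s[[metric]][[lv]]$valid))
        tv <- tv[ok]
        iv <- iv[ok]
        if (length(tv) < 2L) {
          rows[[length(rows) + 1L]] <- data.frame(
            method = method, metric = metric, level = lv, n = length(tv),
            rmse = if (length(tv)) rmse(iv, tv) else NA_real_,
            mean_true = NA_real_, mean_imputed = NA_real_,
            mean_difference = NA_real_, equivalence_bound = NA_real_,
            p_lower = NA_real_, p_upper = NA_real_, equivalent = NA)
          next
        }
        eq <- equivalence_test(iv, tv)
        rows[[length(rows) + 1L]] <- data.frame(
          method = method, metric = metric, level = lv, n = eq$n,
          rmse = rmse(iv, tv), mean_true = eq$mean_true,
          mean_imputed = eq$mean_imputed,
          mean_difference = eq$mean_difference,
          equivalence_bound = eq$equivalence_bound,
          p_lower = eq$p_lower, p_upper = eq$p_upper,
          equivalent = eq$equivalent)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "inserted_fraction") <- mean(ins_frac)
  out
}

#' Simulation study 2: incremental missingness windows
#'
#' For each of ten missingness windows the number of inserted gap periods per
#' participant is drawn uniformly from `{10(w-1), ..., 10w}`; each simulation
#' masks every participant, applies each method, and records the 14-day
#' (period-level) error per participant and the cross-participant RMSE.
#'
#' @param cohort List of complete 14-day `participant_series`.
#' @param methods Subset of `c("nohow", "kalman", "individual_mi")`.
#' @param metrics Subset of [metric_names()].
#' @param windows Window indices to run (default 1:10).
#' @param sims_per_window Simulations per window (default 20).
#' @param seed Integer root seed; required.
#' @param mi_m,mi_k Multiple imputation parameters.
#' @return Object of class `study2_result`: list with `summary` (one row per
#'   window x sim x method x metric: `rmse`, `n`, `inserted_fraction`) and
#'   `details` (per-participant true and imputed period values).
#' @export
run_study2 <- function(cohort, methods = c("nohow", "kalman", "individual_mi"),
                       metrics = c("steps", "tdee"), windows = 1:10,
                       sims_per_window = 20L, seed, mi_m = 7L, mi_k = 5L) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  methods <- match.arg(methods, c("nohow", "kalman", "individual_mi"),
                       several.ok = TRUE)
  metrics <- match.arg(metrics, metric_names(), several.ok = TRUE)
  np <- length(cohort)
  ids <- vapply(cohort, series_id, "")
  true_sum <- lapply(cohort, summarize_all, method = "plain",
                     metrics = metrics)
  srows <- list()
  drows <- list()
  for (w in windows) {
    for (s in seq_len(sims_per_window)) {
      masked <- vector("list", np)
      frac <- numeric(np)
      for (i in seq_len(np)) {
        k <- study2_period_count(w, seed = derive_seed(seed, w, s, i, 11L))
        plan <- draw_plan(k, nrow(cohort[[i]]), 120L,
                          seed = derive_seed(seed, w, s, i, 13L))
        ap <- apply_plan(cohort[[i]], plan)
        masked[[i]] <- ap$masked
        frac[i] <- mean(ap$inserted)
      }
      for (method in methods) {
        vals <- lapply(seq_len(np), function(i) {
          sm <- switch(method,
            nohow = summarize_all(masked[[i]], "nohow", metrics),
            kalman = average_summaries(
              lapply(impute_kalman(masked[[i]])$completions,
                     summarize_all, method = "plain", metrics = metrics)),
            individual_mi = average_summaries(
              lapply(impute_multiple_pmm(masked[[i]], "individual", m = mi_m,
                                         k = mi_k,
                                         seed = derive_seed(seed, w, s, i, 17L)
                     )$completions,
                     summarize_all, method = "plain", metrics = metrics)))
          sm
        })
        for (metric in metrics) {
          tv <- vapply(true_sum, function(x) x[[metric]]$period$value, 0)
          iv <- vapply(vals, function(x) x[[metric]]$period$value, 0)
          ok <- vapply(vals, function(x) isTRUE(x[[metric]]$period$valid), TRUE)
          drows[[length(drows) + 1L]] <- data.frame(
            window = w, sim = s, participant = ids, method = method,
            metric = metric, true = tv, imputed = iv, valid = ok,
            inserted_fraction = frac)
          srows[[length(srows) + 1L]] <- data.frame(
            window = w, sim = s, method = method, metric = metric,
            n = sum(ok),
            rmse = if (sum(ok) > 0) rmse(iv[ok], tv[ok]) else NA_real_,
            inserted_fraction = mean(frac))
        }
      }
    }
  }
  out <- list(summary = do.call(rbind, srows),
              details = do.call(rbind, drows))
  rownames(out$summary) <- rownames(out$details) <- NULL
  class(out) <- "study2_result"
  out
}

#' @export
print.study2_result <- function(x, ...) {
  agg <- stats::aggregate(rmse ~ window + method + metric, x$summary, mean)
  cat("<study2_result>", nrow(x$summary), "window-sim cells\n")
  cat("mean RMSE per window:\n")
  print(stats::reshape(agg, direction = "wide", idvar = c("method", "metric"),
                       timevar = "window"), row.names = FALSE)
  invisible(x)
}
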