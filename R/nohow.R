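#' Per-minute metric values
#'
#' Maps a series to the per-minute summand of a metric: steps/min for
#' `steps`, kcal/min for `tdee`, and a 0/1 category indicator for the four
#' intensity metrics (classified from heart rate via %HRR). Non-worn minutes
#' are `NA` for every metric.
#'
#' @param series A `participant_series`.
#' @param metric One of [metric_names()].
#' @param profile `intensity_profile`, required for the category metrics
#'   (default: derived from the series).
#' @return Numeric vector, one value per minute.
#' @export
minute_values <- function(series, metric, profile = NULL) {
  metric <- match.arg(metric, metric_names())
  worn <- detect_nonwear(series)
  v <- rep(NA_real_, nrow(series))
  if (metric == "steps") {
    v[worn] <- as.numeric(series$steps[worn])
  } else if (metric == "tdee") {
    v[worn] <- series$kcal[worn]
  } else {
    if (is.null(profile)) profile <- intensity_profile(series)
    cats <- classify_minute(percent_hrr(series$heart_rate[worn], profile))
    v[worn] <- as.numeric(cats == metric)
  }
  v
}

#' Scale one hour's worth of minutes by wear time
#'
#' The hourly step of the scaling algorithm: if fewer than `min_minutes`
#' minutes are worn the hour is invalid; otherwise the observed total is
#' divided by the wear proportion (worn minutes / 60), extrapolating to the
#' full hour.
#'
#' @param x Numeric vector of up to 60 per-minute values; `NA` = missing.
#' @param min_minutes Minimum worn minutes for a valid hour (default 5).
#' @return List with `value` (`NA` when invalid), `valid`, `wear_fraction`
#'   and `n_units_used` (worn minutes).
#' @export
scale_hour <- function(x, min_minutes = 5L) {
  if (length(x) > 60L) stop("an hour has at most 60 minutes")
  n <- sum(!is.na(x))
  valid <- n >= min_minutes
  list(value = if (valid) sum(x, na.rm = TRUE) / (n / 60) else NA_real_,
       valid = valid, wear_fraction = n / 60, n_units_used = n)
}

#' Scale one day's worth of scaled hourly totals
#'
#' The daily step: if fewer than `min_hours` of the 24 hours are valid the day
#' is invalid; otherwise the sum of the valid hours' scaled totals is divided
#' by the wear proportion (valid hours / 24).
#'
#' @param hour_values Numeric vector of 24 scaled hourly totals; `NA` marks an
#'   invalid (removed) hour.
#' @param min_hours Minimum valid hours for a valid day (default 18).
#' @return List as in [scale_hour()]; `n_units_used` counts valid hours.
#' @export
scale_day <- function(hour_values, min_hours = 18L) {
  if (length(hour_values) != 24L) stop("a day has 24 hours")
  n <- sum(!is.na(hour_values))
  valid <- n >= min_hours
  list(value = if (valid) sum(hour_values, na.rm = TRUE) / (n / 24) else NA_real_,
       valid = valid, wear_fraction = n / 24, n_units_used = n)
}

#' Average valid days over a 14-day period
#'
#' The period step: the period is invalid when fewer than `min_days` days are
#' valid or fewer than `min_weekend` valid days fall on a Saturday or Sunday;
#' otherwise the value is the mean over valid days.
#'
#' @param day_values Numeric vector of 14 scaled daily totals; `NA` marks an
#'   invalid day.
#' @param weekend Logical vector of length 14; `TRUE` for Saturday/Sunday.
#' @param min_days Minimum valid days (default 4).
#' @param min_weekend Minimum valid weekend days (default 1).
#' @return List as in [scale_hour()]; `n_units_used` counts valid days.
#' @export
summarize_period <- function(day_values, weekend, min_days = 4L,
                             min_weekend = 1L) {
  if (length(day_values) != length(weekend)) {
    stop("day_values and weekend must have equal length")
  }
  ok <- !is.na(day_values)
  valid <- sum(ok) >= min_days && sum(ok & weekend) >= min_weekend
  list(value = if (valid) mean(day_values[ok]) else NA_real_,
       valid = valid, wear_fraction = mean(ok), n_units_used = sum(ok))
}

## hourly worn sums/counts for one metric: df(date, hour, total, n_worn)
hourly_totals <- function(series, metric, profile = NULL) {
  v <- minute_values(series, metric, profile)
  date <- minute_date(series)
  hour <- minute_hour(series)
  key <- factor(paste(date, sprintf("%02d", hour)),
                levels = unique(paste(date, sprintf("%02d", hour))))
  worn <- !is.na(v)
  data.frame(
    date = as.Date(tapply(as.character(date), key, `[`, 1L)),
    hour = as.integer(tapply(hour, key, `[`, 1L)),
    total = as.numeric(rowsum(ifelse(worn, v, 0), key)),
    n_worn = as.integer(rowsum(as.numeric(worn), key)),
    row.names = NULL
  )
}

summary_frame <- function(level, metric, keys, value, valid, wear_fraction,
                          n_units_used) {
  out <- data.frame(level = level, metric = metric)
  out <- cbind(out, keys)
  out$value <- value
  out$valid <- valid
  out$wear_fraction <- wear_fraction
  out$n_units_used <- n_units_used
  out
}

#' Wear-time-scaled activity summaries
#'
#' Applies the full scaling algorithm to a series: hourly totals are scaled by
#' wear proportion (hours with fewer than `min_minutes` worn minutes are
#' removed), scaled hourly totals are summed and rescaled into daily totals
#' (days with fewer than `min_hours` valid hours are removed), and the 14-day
#' value is the mean over valid days provided at least `min_days` days and
#' `min_weekend` weekend day are valid. Category metrics scale per-minute
#' category indicators, yielding scaled minutes in the category.
#'
#' @param series A `participant_series` (14 whole days for `level = "period"`).
#' @param metric One of [metric_names()].
#' @param level `"hour"`, `"day"` or `"period"`.
#' @param profile Optional `intensity_profile` for category metrics.
#' @param min_minutes,min_hours,min_days,min_weekend Validity thresholds.
#' @return Data frame of summaries, one row per unit at the requested level,
#'   with columns `level`, `metric`, time keys, `value`, `valid`,
#'   `wear_fraction` and `n_units_used`. Invalid units carry `value = NA`.
#' @export
nohow_summary <- function(series, metric, level = c("hour", "day", "period"),
                          profile = NULL, min_minutes = 5L, min_hours = 18L,
                          min_days = 4L, min_weekend = 1L) {
  level <- match.arg(level)
  metric <- match.arg(metric, metric_names())
  ht <- hourly_totals(series, metric, profile)
  hvalid <- ht$n_worn >= min_minutes
  hvalue <- ifelse(hvalid, ht$total / (ht$n_worn / 60), NA_real_)
  if (level == "hour") {
    return(summary_frame("hour", metric,
                         data.frame(date = ht$date, hour = ht$hour),
                         hvalue, hvalid, ht$n_worn / 60, ht$n_worn))
  }
  dates <- unique(ht$date)
  nv <- as.integer(rowsum(as.numeric(hvalid), ht$date))
  dsum <- as.numeric(rowsum(ifelse(hvalid, hvalue, 0), ht$date))
  dvalid <- nv >= min_hours
  dvalue <- ifelse(dvalid, dsum / (nv / 24), NA_real_)
  if (level == "day") {
    return(summary_frame("day", metric, data.frame(date = dates),
                         dvalue, dvalid, nv / 24, nv))
  }
  if (length(dates) != 14L) stop("period level requires exactly 14 days")
  per <- summarize_period(dvalue, is_weekend(dates), min_days, min_weekend)
  summary_frame("period", metric,
                data.frame(start_date = dates[1L]),
                per$value, per$valid, per$wear_fraction, per$n_units_used)
}

#' Unadjusted (removal) activity summaries
#'
#' The no-adjustment comparator: plain sums of the observed worn minutes per
#' hour or day and the plain mean of daily sums over the period, with no
#' wear-time scaling and no validity screening. Missing minutes implicitly
#' contribute zero activity.
#'
#' @inheritParams nohow_summary
#' @return Data frame in the same shape as [nohow_summary()]; every unit is
#'   marked valid.
#' @export
removal_summary <- function(series, metric, level = c("hour", "day", "period"),
                            profile = NULL) {
  level <- match.arg(level)
  metric <- match.arg(metric, metric_names())
  ht <- hourly_totals(series, metric, profile)
  if (level == "hour") {
    return(summary_frame("hour", metric,
                         data.frame(date = ht$date, hour = ht$hour),
                         ht$total, TRUE, ht$n_worn / 60, ht$n_worn))
  }
  dates <- unique(ht$date)
  dsum <- as.numeric(rowsum(ht$total, ht$date))
  nworn <- as.integer(rowsum(ht$n_worn, ht$date))
  if (level == "day") {
    return(summary_frame("day", metric, data.frame(date = dates),
                         dsum, TRUE, nworn / 1440, nworn))
  }
  summary_frame("period", metric, data.frame(start_date = dates[1L]),
                mean(dsum), TRUE, sum(nworn) / (1440 * length(dates)),
                length(dates))
}
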