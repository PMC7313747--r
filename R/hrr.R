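#' Age-predicted maximum heart rate (Tanaka equation)
#'
#' @param age Age in years, between 18 and 100.
#' @return Predicted maximum heart rate in bpm: `208 - 0.7 * age`.
#' @export
#' @examples
#' max_heart_rate(40) # 180
max_heart_rate <- function(age) {
  if (any(age < 18 | age > 100)) stop("age must be in [18, 100]")
  208 - 0.7 * age
}

#' Sleeping heart rate from night-time minutes
#'
#' The sleeping heart rate is the minimum, over every window of 20 consecutive
#' minutes falling between 00:00 and 07:59 with heart rate present and fewer
#' than 5 steps in each minute, of the window's mean heart rate. All nights of
#' the series are pooled; windows containing any missing heart-rate minute are
#' skipped, and a window may not cross 07:59 into the next night.
#'
#' @param series A `participant_series`.
#' @param window Window length in minutes (default 20).
#' @param step_threshold Steps-per-minute ceiling for a "low movement" minute
#'   (default 5, i.e. minutes with steps < 5 qualify).
#' @return Sleeping heart rate in bpm.
#' @export
sleeping_heart_rate <- function(series, window = 20L, step_threshold = 5) {
  hr <- series$heart_rate
  eligible <- !is.na(hr) & minute_hour(series) < 8L &
    !is.na(series$steps) & series$steps < step_threshold
  n <- length(hr)
  if (n < window) stop("series shorter than the scan window")
  run <- stats::filter(as.numeric(eligible), rep(1, window), sides = 1)
  hr0 <- ifelse(is.na(hr), 0, hr)
  cs <- cumsum(hr0)
  wsum <- cs - c(rep(0, window), cs[seq_len(n - window)])
  ok <- !is.na(run) & run == window
  if (!any(ok)) {
    stop("no qualifying sleep window: need ", window, " consecutive minutes ",
         "between 00:00 and 07:59 with heart rate present and steps < ",
         step_threshold, "; supply a resting heart rate directly instead")
  }
  min(wsum[ok]) / window
}

#' Resting heart rate from sleeping heart rate
#'
#' Approximates resting heart rate as an 8% increase over sleeping heart rate.
#'
#' @param hr_sleep Sleeping heart rate in bpm (> 0).
#' @return Resting heart rate in bpm: `1.08 * hr_sleep`.
#' @export
resting_heart_rate <- function(hr_sleep) {
  if (any(hr_sleep <= 0)) stop("hr_sleep must be positive")
  1.08 * hr_sleep
}

#' Participant-level heart-rate anchors for intensity classification
#'
#' Builds the per-participant profile holding the maximum, sleeping and
#' resting heart rates that anchor the heart-rate-reserve (%HRR) scale.
#' Either pass a series (age is taken from its attributes and sleeping heart
#' rate is estimated with [sleeping_heart_rate()]) or supply `age` and
#' `hr_sleep` directly.
#'
#' @param series Optional `participant_series`.
#' @param age Age in years (required when `series` is NULL).
#' @param hr_sleep Sleeping heart rate in bpm (required when `series` is NULL).
#' @return An object of class `intensity_profile` with fields `hr_max`,
#'   `hr_sleep`, `hr_rest` and `age`.
#' @export
intensity_profile <- function(series = NULL, age = NULL, hr_sleep = NULL) {
  if (!is.null(series)) {
    if (is.null(age)) age <- series_age(series)
    if (is.null(hr_sleep)) hr_sleep <- sleeping_heart_rate(series)
  }
  if (is.null(age) || is.null(hr_sleep)) {
    stop("supply a series, or both age and hr_sleep")
  }
  hr_rest <- resting_heart_rate(hr_sleep)
  hr_max <- max_heart_rate(age)
  if (hr_rest >= hr_max) stop("resting heart rate must be below maximum")
  structure(list(hr_max = hr_max, hr_sleep = hr_sleep, hr_rest = hr_rest,
                 age = age),
            class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf(paste0("<intensity_profile> age %.1f: HRmax %.1f, ",
                     "HRsleep %.1f, HRrest %.1f bpm\n"),
              x$age, x$hr_max, x$hr_sleep, x$hr_rest))
  invisible(x)
}

#' Percentage of heart-rate reserve
#'
#' Expresses a minute's heart rate as its position within the participant's
#' heart-rate reserve: `(hr - hr_rest) / (hr_max - hr_rest) * 100`. Values may
#' be negative (heart rate below rest) or exceed 100.
#'
#' @param hr Heart rate(s) in bpm.
#' @param profile An `intensity_profile`.
#' @return %HRR value(s).
#' @export
percent_hrr <- function(hr, profile) {
  (hr - profile$hr_rest) / (profile$hr_max - profile$hr_rest) * 100
}

#' Classify a minute's relative intensity
#'
#' Cut points on the %HRR scale: sedentary below 20, light in [20, 40),
#' moderate in [40, 60), vigorous at 60 and above (half-open-on-the-left
#' intervals).
#'
#' @param pct %HRR value(s), finite.
#' @return Factor with ordered levels sedentary, light, moderate, vigorous.
#' @export
classify_minute <- function(pct) {
  if (any(!is.finite(pct) & !is.na(pct))) stop("pct must be finite")
  cut(pct, breaks = c(-Inf, 20, 40, 60, Inf), right = FALSE,
      labels = category_names())
}

#' Daily minutes in each intensity category
#'
#' Counts worn minutes per calendar date in each %HRR category; non-worn
#' minutes belong to no category.
#'
#' @param series A `participant_series`.
#' @param profile An `intensity_profile` (default: derived from `series`).
#' @return Data frame with columns `date`, `sedentary`, `light`, `moderate`,
#'   `vigorous`.
#' @export
minutes_by_category <- function(series, profile = intensity_profile(series)) {
  worn <- !is.na(series$heart_rate)
  date <- minute_date(series)
  cats <- classify_minute(percent_hrr(series$heart_rate[worn], profile))
  tab <- table(date = as.character(date[worn]), category = cats)
  out <- data.frame(date = as.Date(sort(unique(as.character(date)))))
  for (cn in category_names()) {
    out[[cn]] <- as.integer(tab[match(as.character(out$date), rownames(tab)), cn])
    out[[cn]][is.na(out[[cn]])] <- 0L
  }
  out
}
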