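## Build a series directly from channel vectors (grid starts at midnight).
make_series <- function(steps, heart_rate, kcal = NULL,
                        start = "2020-01-06", id = "T1", age = 40,
                        sex = "female") {
  n <- length(steps)
  if (is.null(kcal)) kcal <- rep(1, n)
  ts <- as.POSIXct(paste(start, "00:00"), tz = "UTC") + 60 * (seq_len(n) - 1)
  participant_series(ts, steps = steps, heart_rate = heart_rate, kcal = kcal,
                     participant_id = id, age = age, sex = sex)
}

## Constant-channel series spanning whole days.
flat_series <- function(days = 1, steps = 10, hr = 80, kcal = 1.5, ...) {
  n <- days * 1440L
  make_series(rep(steps, n), rep(hr, n), rep(kcal, n), ...)
}

## A small cached 14-day synthetic participant shared across tests.
test_participant <- local({
  cache <- NULL
  function(seed = 42) {
    if (is.null(cache) || seed != 42) {
      s <- generate_participant(participant_profile(), seed = seed,
                                participant_id = paste0("P", seed))
      if (seed == 42) cache <<- s
      return(s)
    }
    cache
  }
})

## Manual gap plan (bypasses the random draw).
manual_plan <- function(start_minute, length) {
  plan <- data.frame(start_minute = as.integer(start_minute),
                     length = as.integer(length))
  class(plan) <- c("missingness_plan", "data.frame")
  plan
}

## Exhaustive sleeping-heart-rate oracle: scan every 20-minute window.
sleeping_hr_oracle <- function(series, window = 20L, step_threshold = 5) {
  hr <- series$heart_rate
  hour <- as.integer(format(series$timestamp, "%H"))
  n <- length(hr)
  best <- Inf
  for (i in seq_len(n - window + 1L)) {
    ix <- i:(i + window - 1L)
    if (all(!is.na(hr[ix]) & hour[ix] < 8 & !is.na(series$steps[ix]) &
              series$steps[ix] < step_threshold)) {
      best <- min(best, mean(hr[ix]))
    }
  }
  if (!is.finite(best)) stop("oracle: no window")
  best
}
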