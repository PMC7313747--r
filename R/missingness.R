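#' Detect non-wear minutes
#'
#' Non-wear is defined by the absence of a heart-rate reading: the returned
#' mask is `TRUE` (worn) exactly where `heart_rate` is present.
#'
#' @param series A `participant_series`.
#' @return Logical vector, one element per minute.
#' @export
detect_nonwear <- function(series) {
  !is.na(series$heart_rate)
}

#' Draw a random gap-insertion plan
#'
#' Draws `n_periods` independent non-wear periods: start minutes uniform over
#' the series and integer lengths uniform on `{1, ..., max_len}`. Periods may
#' overlap (they are applied as a union) and periods extending past the series
#' end are truncated there.
#'
#' @param n_periods Number of periods (>= 0).
#' @param series_length Series length in minutes.
#' @param max_len Maximum period length in minutes (default 120).
#' @param seed Integer seed; required.
#' @return An object of class `missingness_plan`: a data frame with columns
#'   `start_minute` (0-based) and `length`, with the draw parameters attached
#'   as attributes.
#' @export
draw_plan <- function(n_periods, series_length, max_len = 120L, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  if (max_len < 1) stop("max_len must be >= 1")
  if (n_periods < 0) stop("n_periods must be >= 0")
  set.seed(seed)
  n_periods <- as.integer(n_periods)
  plan <- data.frame(
    start_minute = if (n_periods > 0)
      sample.int(series_length, n_periods, replace = TRUE) - 1L
    else integer(0),
    length = if (n_periods > 0)
      sample.int(as.integer(max_len), n_periods, replace = TRUE)
    else integer(0)
  )
  attr(plan, "n_periods") <- n_periods
  attr(plan, "series_length") <- as.integer(series_length)
  attr(plan, "max_len") <- as.integer(max_len)
  attr(plan, "seed") <- seed
  class(plan) <- c("missingness_plan", "data.frame")
  plan
}

## logical mask (TRUE = blanked) for the union of plan intervals
plan_mask <- function(plan, n) {
  mask <- logical(n)
  for (i in seq_len(nrow(plan))) {
    s <- plan$start_minute[i] + 1L
    if (s > n) next
    mask[s:min(n, s + plan$length[i] - 1L)] <- TRUE
  }
  mask
}

#' Apply a gap-insertion plan to a series
#'
#' Blanks all three channels (steps, heart rate, kcal) on the union of the
#' plan's intervals, simulating device non-wear. The input series is left
#' untouched.
#'
#' @param series A `participant_series`.
#' @param plan A `missingness_plan` whose indices lie within the series.
#' @return List with elements `masked` (the series with inserted gaps) and
#'   `inserted` (logical; `TRUE` exactly at minutes newly blanked, i.e.
#'   previously worn).
#' @export
apply_plan <- function(series, plan) {
  n <- nrow(series)
  if (nrow(plan) > 0 && any(plan$start_minute < 0 | plan$start_minute >= n)) {
    stop("plan start_minute outside the series")
  }
  mask <- plan_mask(plan, n)
  inserted <- mask & detect_nonwear(series)
  masked <- series
  masked$steps[mask] <- NA_real_
  masked$heart_rate[mask] <- NA_real_
  masked$kcal[mask] <- NA_real_
  list(masked = masked, inserted = inserted)
}

#' Number of inserted periods for a missingness window
#'
#' The incremental-missingness design uses ten windows; window `w` draws the
#' number of inserted periods uniformly from `{10(w-1), ..., 10w}` (window 1:
#' 0-10 periods, window 10: 90-100 periods).
#'
#' @param window_index Window number, 1-10.
#' @param seed Integer seed; required.
#' @return Integer period count.
#' @export
study2_period_count <- function(window_index, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  if (window_index < 1 || window_index > 10) stop("window_index must be in 1..10")
  set.seed(seed)
  lo <- 10L * (as.integer(window_index) - 1L)
  sample(seq(lo, lo + 10L), 1L)
}
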