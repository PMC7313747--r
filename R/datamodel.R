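CSV_HEADER <- c("participant_id", "age", "sex", "timestamp", "steps",
                "heart_rate", "kcal")
MINUTES_14D <- 14L * 1440L

#' Physical activity metrics
#'
#' The closed set of metric names understood by the summarisation and
#' evaluation functions: `steps` (count), `tdee` (total daily energy
#' expenditure, kcal) and the four heart-rate-reserve intensity categories
#' (`sedentary`, `light`, `moderate`, `vigorous`, minutes).
#'
#' @return Character vector of the six metric names.
#' @export
metric_names <- function() {
  c("steps", "tdee", "sedentary", "light", "moderate", "vigorous")
}

#' Intensity category names
#' @return Character vector of the four category names, ordered by intensity.
#' @export
category_names <- function() c("sedentary", "light", "moderate", "vigorous")

#' Construct a minute-level participant series
#'
#' A `participant_series` is a data frame with one row per calendar minute and
#' columns `timestamp` (minute precision), `steps`, `heart_rate` and `kcal`,
#' carrying `participant_id`, `age` and `sex` as attributes. Missingness is
#' encoded per channel as `NA`; a minute with no heart-rate reading is
#' non-wear, and all channels of a non-worn minute are treated as missing by
#' every downstream consumer.
#'
#' @param timestamp POSIXct vector forming a complete, strictly increasing
#'   1-minute grid starting at midnight of the first day.
#' @param steps Non-negative step counts per minute (`NA` = missing).
#' @param heart_rate Heart rate in bpm, inside (25, 250) when present;
#'   `NA` encodes non-wear.
#' @param kcal Energy expenditure in kcal per minute (`NA` = missing).
#' @param participant_id Opaque identifier string.
#' @param age Age in years.
#' @param sex `"female"` or `"male"`.
#' @param validate Run the series validator (default `TRUE`).
#' @return An object of class `participant_series`.
#' @export
participant_series <- function(timestamp, steps, heart_rate, kcal,
                               participant_id, age, sex, validate = TRUE) {
  df <- data.frame(timestamp = timestamp,
                   steps = as.numeric(steps),
                   heart_rate = as.numeric(heart_rate),
                   kcal = as.numeric(kcal))
  attr(df, "participant_id") <- as.character(participant_id)
  attr(df, "age") <- as.numeric(age)
  attr(df, "sex") <- match.arg(as.character(sex), c("female", "male"))
  class(df) <- c("participant_series", "data.frame")
  if (validate) validate_series(df)
  df
}

#' Validate a participant series
#'
#' Checks the minute-grid and channel-range invariants: a complete, strictly
#' increasing 1-minute grid starting at midnight; `steps >= 0` and `kcal >= 0`
#' when present; heart rate inside (25, 250) bpm when present. In `"14-day"`
#' mode the series must contain exactly 20160 minutes.
#'
#' @param series A `participant_series`.
#' @param mode `"free"` (any whole number of days) or `"14-day"`.
#' @return The series, invisibly. Errors describe the first violation found.
#' @export
validate_series <- function(series, mode = c("free", "14-day")) {
  mode <- match.arg(mode)
  ts <- series$timestamp
  n <- length(ts)
  if (n == 0L) stop("series is empty")
  if (mode == "14-day" && n != MINUTES_14D) {
    stop("14-day mode requires exactly ", MINUTES_14D, " rows, got ", n)
  }
  if (anyNA(ts)) stop("series contains unparsed timestamps")
  d <- diff(as.numeric(ts))
  if (any(d <= 0)) {
    i <- which(d <= 0)[1L]
    stop("timestamps not strictly increasing at row ", i + 1L,
         " (", format(ts[i + 1L], "%Y-%m-%dT%H:%M"), ")")
  }
  if (any(d != 60)) {
    i <- which(d != 60)[1L]
    stop("minute grid has a gap: first absent minute is ",
         format(ts[i] + 60, "%Y-%m-%dT%H:%M"))
  }
  if (format(ts[1L], "%H:%M") != "00:00") {
    stop("series must start at midnight of day 1, got ",
         format(ts[1L], "%H:%M"))
  }
  if (any(series$steps < 0, na.rm = TRUE)) {
    stop("negative steps at row ", which(series$steps < 0)[1L])
  }
  if (any(series$kcal < 0, na.rm = TRUE)) {
    stop("negative kcal at row ", which(series$kcal < 0)[1L])
  }
  hr <- series$heart_rate
  bad <- !is.na(hr) & (hr <= 25 | hr >= 250)
  if (any(bad)) {
    stop("heart rate outside (25, 250) bpm at row ", which(bad)[1L])
  }
  invisible(series)
}

#' @export
print.participant_series <- function(x, ...) {
  worn <- !is.na(x$heart_rate)
  cat("<participant_series> ", attr(x, "participant_id"),
      " (", attr(x, "sex"), ", age ", attr(x, "age"), ")\n", sep = "")
  cat("  ", nrow(x), " minutes from ",
      format(x$timestamp[1], "%Y-%m-%d %H:%M"), " to ",
      format(x$timestamp[nrow(x)], "%Y-%m-%d %H:%M"), "\n", sep = "")
  cat(sprintf("  wear time: %d/%d minutes (%.1f%%)\n",
              sum(worn), nrow(x), 100 * mean(worn)))
  invisible(x)
}

#' @export
summary.participant_series <- function(object, ...) {
  worn <- !is.na(object$heart_rate)
  day <- as.Date(object$timestamp)
  out <- data.frame(
    date = sort(unique(day)),
    worn_minutes = as.integer(rowsum(as.numeric(worn), day)),
    steps = as.numeric(rowsum(ifelse(worn, object$steps, 0), day)),
    kcal = as.numeric(rowsum(ifelse(worn, object$kcal, 0), day))
  )
  rownames(out) <- NULL
  out
}

#' @export
plot.participant_series <- function(x, channel = c("steps", "heart_rate", "kcal"),
                                    ...) {
  channel <- match.arg(channel)
  graphics::plot(x$timestamp, x[[channel]], type = "l", xlab = "time",
                 ylab = channel, ...)
  invisible(x)
}

series_id <- function(series) attr(series, "participant_id")
series_age <- function(series) attr(series, "age")
series_sex <- function(series) attr(series, "sex")

## per-minute clock hour (0-23) and calendar date
minute_hour <- function(series) as.integer(format(series$timestamp, "%H"))
minute_date <- function(series) as.Date(format(series$timestamp, "%Y-%m-%d"))
is_weekend <- function(dates) format(dates, "%u") %in% c("6", "7")

num_cell <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))

#' Write a participant series to CSV
#'
#' The dialect is one row per minute with header
#' `participant_id,age,sex,timestamp,steps,heart_rate,kcal`, ISO-8601
#' timestamps at minute precision, and missing channel values as empty cells
#' (never numeric sentinels). Numeric channels are written with full precision
#' so that [read_series()] reproduces the series bit-exactly.
#'
#' @param series A valid `participant_series`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  out <- data.frame(
    participant_id = series_id(series),
    age = num_cell(rep(series_age(series), nrow(series))),
    sex = series_sex(series),
    timestamp = format(series$timestamp, "%Y-%m-%dT%H:%M"),
    steps = num_cell(series$steps),
    heart_rate = num_cell(series$heart_rate),
    kcal = num_cell(series$kcal),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a participant series from CSV
#'
#' Inverse of [write_series()]. Raises on malformed timestamps (naming the
#' row), duplicate or out-of-order timestamps, gaps in the minute grid (naming
#' the first absent minute) and negative counts. In `"14-day"` mode the file
#' must contain exactly 20160 rows.
#'
#' @param path CSV file in the [write_series()] dialect.
#' @param mode `"free"` or `"14-day"`.
#' @return A `participant_series`.
#' @export
read_series <- function(path, mode = c("free", "14-day")) {
  mode <- match.arg(mode)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!identical(names(raw), CSV_HEADER)) {
    stop("unexpected CSV header: ", paste(names(raw), collapse = ","))
  }
  ts <- as.POSIXct(raw$timestamp, format = "%Y-%m-%dT%H:%M", tz = "UTC")
  if (anyNA(ts)) {
    stop("malformed timestamp at row ", which(is.na(ts))[1L],
         ": '", raw$timestamp[which(is.na(ts))[1L]], "'")
  }
  blank_na <- function(x) as.numeric(ifelse(x == "", NA, x))
  series <- participant_series(
    timestamp = ts,
    steps = blank_na(raw$steps),
    heart_rate = blank_na(raw$heart_rate),
    kcal = blank_na(raw$kcal),
    participant_id = raw$participant_id[1L],
    age = as.numeric(raw$age[1L]),
    sex = raw$sex[1L],
    validate = FALSE
  )
  validate_series(series, mode = mode)
  series
}

#' Replace the channel values of a series
#'
#' Internal helper returning a copy of `series` with new channel columns;
#' attributes and timestamps are preserved.
#' @noRd
set_channels <- function(series, steps = NULL, heart_rate = NULL, kcal = NULL) {
  if (!is.null(steps)) series$steps <- steps
  if (!is.null(heart_rate)) series$heart_rate <- heart_rate
  if (!is.null(kcal)) series$kcal <- kcal
  series
}
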