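#' Behavioural profile of a synthetic participant
#'
#' Parameters of the circadian simulation model used by
#' [generate_participant()]: a fixed nightly sleep window with steps = 0 and
#' quiet heart rate; Poisson sedentary "fidget" steps outside activity bouts;
#' activity bouts arriving as a Poisson process with uniform lengths and
#' cadences; heart rate coupled linearly to cadence within the participant's
#' heart-rate reserve plus AR(1) noise; and energy expenditure as a linear
#' function of cadence above a basal rate.
#'
#' When `bout_rate` is `NULL` (the default) it is derived from
#' `target_daily_steps` by solving the Poisson-coverage equation
#' `target = waking * ((1 - exp(-lambda)) * E[cadence] + exp(-lambda) * sedentary_step_rate)`
#' for the bout intensity `lambda`, which compensates for overlapping bouts.
#'
#' @param age Age in years.
#' @param sex `"female"` or `"male"`.
#' @param sleep_window Character vector `c(start, end)` of clock times
#'   (`"HH:MM"`); the window may cross midnight. Default 23:00-07:00.
#' @param sleep_hr Mean sleeping heart rate, bpm.
#' @param target_daily_steps Expected total steps per day.
#' @param bout_rate Expected activity bouts per day, or `NULL` to derive from
#'   `target_daily_steps`.
#' @param bout_length_range Bout length range in minutes, `c(low, high)`.
#' @param bout_cadence_range Bout cadence range in steps/min, `c(low, high)`.
#' @param sedentary_step_rate Mean steps/min outside bouts while awake.
#' @param waking_hr_uplift Heart-rate elevation (bpm) of quiet waking minutes
#'   over the resting anchor.
#' @param hr_noise_sd Marginal SD (bpm) of the AR(1) waking heart-rate noise.
#' @param sleep_hr_noise_sd SD (bpm) of sleeping heart-rate noise.
#' @param ar_coef AR(1) coefficient of the waking heart-rate noise.
#' @param peak_cadence Cadence (steps/min) mapped to 90% of heart-rate
#'   reserve; also scales the energy model.
#' @param basal_kcal_per_min Basal energy expenditure, kcal/min.
#' @return An object of class `participant_profile`.
#' @export
participant_profile <- function(age = 47, sex = "female",
                                sleep_window = c("23:00", "07:00"),
                                sleep_hr = 55,
                                target_daily_steps = 10500,
                                bout_rate = NULL,
                                bout_length_range = c(10, 40),
                                bout_cadence_range = c(50, 110),
                                sedentary_step_rate = 2,
                                waking_hr_uplift = 16,
                                hr_noise_sd = 7,
                                sleep_hr_noise_sd = 2.5,
                                ar_coef = 0.8,
                                peak_cadence = 180,
                                basal_kcal_per_min = 1.55) {
  p <- list(age = age, sex = match.arg(sex, c("female", "male")),
            sleep_window = sleep_window, sleep_hr = sleep_hr,
            target_daily_steps = target_daily_steps, bout_rate = bout_rate,
            bout_length_range = bout_length_range,
            bout_cadence_range = bout_cadence_range,
            sedentary_step_rate = sedentary_step_rate,
            waking_hr_uplift = waking_hr_uplift,
            hr_noise_sd = hr_noise_sd, sleep_hr_noise_sd = sleep_hr_noise_sd,
            ar_coef = ar_coef, peak_cadence = peak_cadence,
            basal_kcal_per_min = basal_kcal_per_min)
  class(p) <- "participant_profile"
  validate_profile(p)
  p
}

validate_profile <- function(p) {
  stopifnot(length(p$sleep_window) == 2L)
  rates <- c(p$target_daily_steps, p$sedentary_step_rate, p$hr_noise_sd,
             p$sleep_hr_noise_sd, p$basal_kcal_per_min, p$peak_cadence)
  if (any(rates < 0)) stop("profile rates must be non-negative")
  if (!is.null(p$bout_rate) && p$bout_rate < 0) stop("bout_rate must be >= 0")
  if (p$bout_length_range[1] > p$bout_length_range[2] ||
      p$bout_cadence_range[1] > p$bout_cadence_range[2]) {
    stop("bout ranges must satisfy low <= high")
  }
  hr_rest <- resting_heart_rate(p$sleep_hr)
  hr_max <- max_heart_rate(p$age)
  if (!(p$sleep_hr < hr_rest && hr_rest < hr_max)) {
    stop("need sleep_hr < resting HR < max HR")
  }
  invisible(p)
}

## minutes-into-day for "HH:MM"
clock_to_minute <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)[[1L]]
  as.integer(parts[1L]) * 60L + as.integer(parts[2L])
}

## logical sleep mask over minutes-of-day 0..1439, window may cross midnight
sleep_mask_day <- function(sleep_window) {
  s <- clock_to_minute(sleep_window[1L])
  e <- clock_to_minute(sleep_window[2L])
  mod <- 0:1439
  if (s <= e) mod >= s & mod < e else mod >= s | mod < e
}

## bouts/day solving the coverage equation for the target step count
derive_bout_rate <- function(p, waking_per_day) {
  e_len <- mean(p$bout_length_range)
  e_cad <- mean(p$bout_cadence_range)
  if (e_len <= 0 || e_cad <= p$sedentary_step_rate) return(0)
  target <- p$target_daily_steps
  base <- waking_per_day * p$sedentary_step_rate
  if (target <= base) return(0)
  f <- function(lam) {
    waking_per_day * ((1 - exp(-lam)) * e_cad + exp(-lam) * p$sedentary_step_rate) -
      target
  }
  upper <- 10
  if (f(upper) < 0) return(upper * waking_per_day / e_len)
  lam <- stats::uniroot(f, c(1e-9, upper))$root
  lam * waking_per_day / e_len
}

#' Simulate one participant's minute-level series
#'
#' Generates a complete (no missing minutes) series of `days` x 1440 minutes
#' under the model described in [participant_profile()]. Heart rate is clipped
#' to (25, 250) bpm; energy is
#' `basal_kcal_per_min * (1 + 4 * steps / peak_cadence)` kcal/min.
#'
#' @param profile A `participant_profile`.
#' @param seed Integer seed; required (reproducibility contract).
#' @param participant_id Identifier for the series.
#' @param start_date First calendar date (default a Monday).
#' @param days Number of days (default 14).
#' @return A complete `participant_series`.
#' @export
generate_participant <- function(profile, seed, participant_id = "P1",
                                 start_date = "2020-01-06", days = 14L) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  validate_profile(profile)
  set.seed(seed)
  n <- as.integer(days) * 1440L
  ts <- as.POSIXct(paste(start_date, "00:00"), tz = "UTC") +
    60 * (seq_len(n) - 1)
  sleep <- rep(sleep_mask_day(profile$sleep_window), days)
  waking_per_day <- sum(!sleep) / days

  hr_max <- max_heart_rate(profile$age)
  hr_rest <- resting_heart_rate(profile$sleep_hr)
  reserve <- hr_max - hr_rest

  bout_rate <- profile$bout_rate
  if (is.null(bout_rate)) bout_rate <- derive_bout_rate(profile, waking_per_day)

  ## lay down bouts: later bouts overwrite overlaps; truncated at series end
  cadence <- numeric(n)
  n_bouts <- stats::rpois(1L, bout_rate * days)
  if (n_bouts > 0) {
    waking_idx <- which(!sleep)
    starts <- sample(waking_idx, n_bouts, replace = TRUE)
    lens <- sample(seq(profile$bout_length_range[1L], profile$bout_length_range[2L]),
                   n_bouts, replace = TRUE)
    cads <- stats::runif(n_bouts, profile$bout_cadence_range[1L],
                         profile$bout_cadence_range[2L])
    for (i in seq_len(n_bouts)) {
      ix <- starts[i]:min(n, starts[i] + lens[i] - 1L)
      cadence[ix] <- cads[i]
    }
  }
  cadence[sleep] <- 0

  steps <- integer(n)
  quiet <- !sleep & cadence == 0
  steps[quiet] <- stats::rpois(sum(quiet), profile$sedentary_step_rate)
  inb <- cadence > 0
  steps[inb] <- stats::rpois(sum(inb), cadence[inb])

  ar_innov_sd <- profile$hr_noise_sd * sqrt(1 - profile$ar_coef^2)
  noise <- as.numeric(stats::filter(stats::rnorm(n, 0, ar_innov_sd),
                                    profile$ar_coef, method = "recursive"))
  hr <- hr_rest + profile$waking_hr_uplift * (cadence == 0) +
    (steps / profile$peak_cadence) * reserve * 0.9 + noise
  hr[sleep] <- stats::rnorm(sum(sleep), profile$sleep_hr,
                            profile$sleep_hr_noise_sd)
  hr <- pmin(pmax(hr, 25 + 1e-3), 250 - 1e-3)

  kcal <- profile$basal_kcal_per_min * (1 + 4 * steps / profile$peak_cadence)

  participant_series(timestamp = ts, steps = steps, heart_rate = hr,
                     kcal = kcal, participant_id = participant_id,
                     age = profile$age, sex = profile$sex)
}

#' Configuration for a synthetic cohort
#'
#' Describes the population distributions from which per-participant profiles
#' are drawn: truncated normals for age, sleeping heart rate, target daily
#' steps and basal energy, and a Bernoulli sex indicator. Defaults emulate a
#' middle-aged, predominantly female weight-loss-maintenance cohort.
#'
#' @param n_participants Number of participants (>= 1).
#' @param seed Integer root seed; required, fixes the cohort bit-exactly.
#' @param age_mean,age_sd,age_range Truncated-normal parameters for age.
#' @param p_female Probability of female sex.
#' @param sleep_hr_mean,sleep_hr_sd,sleep_hr_range Sleeping heart rate (bpm).
#' @param steps_mean,steps_sd,steps_range Target daily steps.
#' @param basal_mean,basal_sd,basal_range Basal energy (kcal/min).
#' @param days Days per participant (default 14).
#' @param ... Fixed [participant_profile()] arguments applied to everyone.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants, seed,
                          age_mean = 47.46, age_sd = 9.62,
                          age_range = c(22, 75),
                          p_female = 93 / 109,
                          sleep_hr_mean = 55, sleep_hr_sd = 5,
                          sleep_hr_range = c(40, 75),
                          steps_mean = 10570, steps_sd = 3209,
                          steps_range = c(3200, 20000),
                          basal_mean = 1.55, basal_sd = 0.15,
                          basal_range = c(1.0, 2.2),
                          days = 14L, ...) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  if (n_participants < 1) stop("n_participants must be >= 1")
  structure(list(n_participants = as.integer(n_participants),
                 seed = as.integer(seed),
                 age = list(mean = age_mean, sd = age_sd, range = age_range),
                 p_female = p_female,
                 sleep_hr = list(mean = sleep_hr_mean, sd = sleep_hr_sd,
                                 range = sleep_hr_range),
                 steps = list(mean = steps_mean, sd = steps_sd,
                              range = steps_range),
                 basal = list(mean = basal_mean, sd = basal_sd,
                              range = basal_range),
                 days = as.integer(days),
                 profile_args = list(...)),
            class = "cohort_config")
}

rtruncnorm <- function(n, spec) {
  lo <- stats::pnorm(spec$range[1L], spec$mean, spec$sd)
  hi <- stats::pnorm(spec$range[2L], spec$mean, spec$sd)
  stats::qnorm(stats::runif(n, lo, hi), spec$mean, spec$sd)
}

#' Generate a synthetic cohort
#'
#' Draws `n_participants` profiles from the population distributions of the
#' config, then simulates each participant with an independently derived seed.
#' The same config (including its seed) reproduces the cohort bit-exactly.
#'
#' @param config A [cohort_config()].
#' @return A list of `participant_series`, named by participant id.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_participants
  ages <- rtruncnorm(n, config$age)
  sexes <- ifelse(stats::runif(n) < config$p_female, "female", "male")
  sleep_hrs <- rtruncnorm(n, config$sleep_hr)
  targets <- rtruncnorm(n, config$steps)
  basals <- rtruncnorm(n, config$basal)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  ids <- sprintf("P%03d", seq_len(n))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    prof <- do.call(participant_profile,
                    c(list(age = ages[i], sex = sexes[i],
                           sleep_hr = sleep_hrs[i],
                           target_daily_steps = targets[i],
                           basal_kcal_per_min = basals[i]),
                      config$profile_args))
    out[[i]] <- generate_participant(prof, seed = seeds[i],
                                     participant_id = ids[i],
                                     days = config$days)
  }
  names(out) <- ids
  out
}
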