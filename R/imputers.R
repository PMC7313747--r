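CHANNELS <- c("steps", "heart_rate", "kcal")

clip_channel <- function(x, channel) {
  if (channel == "heart_rate") pmin(pmax(x, 25 + 1e-6), 250 - 1e-6)
  else pmax(x, 0)
}

new_wear_imputation <- function(completions, method, details = list()) {
  structure(list(completions = completions, method = method,
                 m_datasets = length(completions), details = details),
            class = "wear_imputation")
}

#' @export
print.wear_imputation <- function(x, ...) {
  cat("<wear_imputation> method:", x$method, "-", x$m_datasets,
      "completed dataset(s) of", nrow(x$completions[[1L]]), "minutes\n")
  invisible(x)
}

#' Extract a completed series from an imputation result
#'
#' @param x A `wear_imputation`.
#' @param which Which completed dataset (default 1; multiple imputation
#'   results hold `m` of them).
#' @return A `participant_series` with no missing minutes.
#' @export
completed_series <- function(x, which = 1L) {
  stopifnot(inherits(x, "wear_imputation"))
  x$completions[[which]]
}

channel_args <- function(series) {
  ts <- series$timestamp
  list(wd = factor(format(ts, "%u"), levels = as.character(1:7)),
       hf = factor(minute_hour(series), levels = 0:23))
}

#' Mean imputation
#'
#' Fills every missing minute of each channel with the plain mean of that
#' channel's observed minutes, computed either over the individual's own data
#' or pooled over an entire cohort.
#'
#' @param target A `participant_series` with (possibly) missing minutes.
#' @param scope `"individual"` (the participant's own observed mean) or
#'   `"overall"` (the pooled cohort mean).
#' @param cohort List of `participant_series` whose observed minutes define
#'   the overall means; required when `scope = "overall"`.
#' @return A `wear_imputation` with one completed dataset.
#' @export
impute_mean <- function(target, scope = c("individual", "overall"),
                        cohort = NULL) {
  scope <- match.arg(scope)
  if (scope == "overall" && is.null(cohort)) {
    stop("overall scope requires a cohort")
  }
  out <- target
  for (ch in CHANNELS) {
    pool <- if (scope == "individual") target[[ch]]
            else unlist(lapply(cohort, `[[`, ch), use.names = FALSE)
    if (all(is.na(pool))) stop("channel ", ch, " has no observed minutes in scope")
    mis <- is.na(out[[ch]])
    if (any(mis)) {
      out[[ch]][mis] <- clip_channel(mean(pool, na.rm = TRUE), ch)
    }
  }
  new_wear_imputation(list(out), paste0(scope, "_mean"))
}

## k-nearest-donor matching on predicted values; returns imputed y for pred_mis
pmm_match <- function(pred_obs, y_obs, pred_mis, k) {
  ## random tie-breaking: coarse categorical predictors produce large blocks
  ## of exactly tied predictions, and each missing value must draw its donors
  ## at random from its block rather than from a fixed corner of it. A jitter
  ## many orders below any real prediction difference randomises ranks only.
  eps <- 1e-9 * (diff(range(pred_obs)) + 1)
  pj <- pred_obs + stats::runif(length(pred_obs), -eps, eps)
  pred_mis <- pred_mis + stats::runif(length(pred_mis), -eps, eps)
  o <- order(pj)
  po <- pj[o]
  yo <- y_obs[o]
  n <- length(po)
  pos <- findInterval(pred_mis, po)
  out <- numeric(length(pred_mis))
  for (i in seq_along(pred_mis)) {
    lo <- max(1L, pos[i] - k + 1L)
    hi <- min(n, pos[i] + k)
    cand <- lo:hi
    d <- abs(po[cand] - pred_mis[i])
    keep <- cand[order(d)][seq_len(min(k, length(cand)))]
    out[i] <- yo[keep[sample.int(length(keep), 1L)]]
  }
  out
}

## fit y ~ X on a bootstrap resample of rows `obs`; returns predictions for all rows
pmm_boot_predict <- function(X, y, obs) {
  boot <- obs[sample.int(length(obs), length(obs), replace = TRUE)]
  beta <- stats::lm.fit(X[boot, , drop = FALSE], y[boot])$coefficients
  beta[is.na(beta)] <- 0
  drop(X %*% beta)
}

#' Multiple imputation by bootstrap predictive mean matching
#'
#' For each of `m` imputations: a bootstrap resample of the observed minutes
#' is drawn; a linear predictor of the channel on the covariates is fitted
#' (day-of-week and, in individual scope, hour-of-day as categorical
#' indicators; age and sex additionally in overall scope); and every missing
#' minute copies the observed value of one of the `k` donors whose predictions
#' are nearest its own (chosen at random). Point estimates downstream are the
#' mean of the `m` completed summaries.
#'
#' @param target A `participant_series`, or (in overall scope) a list of them
#'   to impute jointly against the pooled model.
#' @param scope `"individual"` (covariates: hour, weekday; default m = 7) or
#'   `"overall"` (pooled minutes; covariates: age, sex, weekday; default
#'   m = 5).
#' @param m Number of imputations (default by scope).
#' @param cohort Observed-minute pool for overall scope (default: `target`
#'   itself when a list).
#' @param k Donor pool size (default 5).
#' @param seed Integer seed; required.
#' @param channels Channels to impute (default all three).
#' @return A `wear_imputation` with `m` completed datasets (or a list of them
#'   when `target` is a list).
#' @export
impute_multiple_pmm <- function(target, scope = c("individual", "overall"),
                                m = NULL, cohort = NULL, k = 5L, seed,
                                channels = CHANNELS) {
  scope <- match.arg(scope)
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  if (is.null(m)) m <- if (scope == "individual") 7L else 5L
  if (m < 1) stop("m must be >= 1")
  set.seed(seed)
  if (scope == "individual") {
    stopifnot(inherits(target, "participant_series"))
    ca <- channel_args(target)
    X <- stats::model.matrix(~ wd + hf, data = ca)
    res <- pmm_impute_one(list(target), X, list(seq_len(nrow(target))),
                          m, k, channels, "individual_mi")
    return(res[[1L]])
  }
  targets <- if (inherits(target, "participant_series")) list(target) else target
  if (is.null(cohort)) cohort <- targets
  rows <- lapply(cohort, nrow)
  stacked <- data.frame(
    age = rep(vapply(cohort, series_age, 0), unlist(rows)),
    male = rep(as.numeric(vapply(cohort, series_sex, "") == "male"),
               unlist(rows)),
    wd = factor(unlist(lapply(cohort, function(s) format(s$timestamp, "%u"))),
                levels = as.character(1:7))
  )
  X <- stats::model.matrix(~ age + male + wd, data = stacked)
  offsets <- cumsum(c(0L, unlist(rows)))
  idx_of <- function(i) (offsets[i] + 1L):offsets[i + 1L]
  target_pos <- match(vapply(targets, series_id, ""),
                      vapply(cohort, series_id, ""))
  if (anyNA(target_pos)) stop("every target must be present in the cohort")
  res <- pmm_impute_one(cohort, X, lapply(seq_along(cohort), idx_of),
                        m, k, channels, "overall_mi",
                        only = target_pos)
  if (inherits(target, "participant_series")) res[[1L]] else res
}

## shared PMM engine: series_list with design X over stacked rows; imputes the
## series at positions `only` (default all), pooling donors over all rows
pmm_impute_one <- function(series_list, X, row_idx, m, k, channels, method,
                           only = seq_along(series_list)) {
  p <- ncol(X)
  comps <- lapply(only, function(i) replicate(m, series_list[[i]],
                                              simplify = FALSE))
  names(comps) <- vapply(series_list[only], series_id, "")
  for (ch in channels) {
    y <- unlist(lapply(series_list, `[[`, ch), use.names = FALSE)
    obs <- which(!is.na(y))
    mis_by_series <- lapply(only, function(i) {
      ix <- row_idx[[i]]
      ix[is.na(y[ix])]
    })
    if (!any(lengths(mis_by_series) > 0)) next
    if (length(obs) <= p) {
      stop("channel ", ch, ": fewer observed minutes (", length(obs),
           ") than predictor columns (", p, ")")
    }
    for (j in seq_len(m)) {
      pred <- pmm_boot_predict(X, y, obs)
      for (t in seq_along(only)) {
        mis <- mis_by_series[[t]]
        if (length(mis) == 0L) next
        fill <- pmm_match(pred[obs], y[obs], pred[mis], k)
        local_mis <- match(mis, row_idx[[only[t]]])
        comps[[t]][[j]][[ch]][local_mis] <- clip_channel(fill, ch)
      }
    }
  }
  lapply(comps, new_wear_imputation, method = method)
}

#' Kalman smoothing imputation under a local-level model
#'
#' Per channel, fits a Gaussian local-level structural time-series model
#' (random-walk latent level plus observation noise) by maximum likelihood on
#' the observed sequence via [stats::StructTS()], runs the Kalman smoother
#' over the full minute grid treating missing minutes as absent observations
#' ([stats::tsSmooth()]), and fills each missing minute with the smoothed
#' level. Steps and energy are clipped below at 0 and heart rate to (25, 250).
#' A channel whose observed values are constant is filled with that constant
#' (the degenerate limit of the model).
#'
#' @param target A `participant_series` with at least 10 observed minutes per
#'   imputed channel.
#' @param seed Unused (the method is deterministic); accepted for interface
#'   uniformity.
#' @param channels Channels to impute (default all three).
#' @return A `wear_imputation`; `details$fits` holds the fitted level and
#'   observation variances per channel.
#' @export
impute_kalman <- function(target, seed = NULL, channels = CHANNELS) {
  out <- target
  fits <- list()
  for (ch in channels) {
    y <- out[[ch]]
    mis <- is.na(y)
    if (!any(mis)) next
    obs <- y[!mis]
    if (length(obs) < 10L) stop("channel ", ch, ": need >= 10 observed minutes")
    if (stats::var(obs) < 1e-12) {
      out[[ch]][mis] <- clip_channel(obs[1L], ch)
      fits[[ch]] <- c(level = 0, epsilon = 0)
      next
    }
    fit <- tryCatch(stats::StructTS(stats::ts(y), type = "level"),
                    error = function(e) {
                      stop("local-level fit failed for channel ", ch, ": ",
                           conditionMessage(e))
                    })
    if (!is.finite(fit$loglik)) {
      stop("non-finite likelihood for channel ", ch,
           " (variances: ", paste(signif(fit$coef, 4), collapse = ", "), ")")
    }
    level <- as.numeric(stats::tsSmooth(fit)[, 1L])
    out[[ch]][mis] <- clip_channel(level[mis], ch)
    fits[[ch]] <- fit$coef
  }
  new_wear_imputation(list(out), "kalman", details = list(fits = fits))
}

#' Iterative random forest imputation
#'
#' missForest-style chained imputation: missing values are initialised with
#' the channel mean, then for up to `max_iter` rounds each channel is
#' regressed (random forest, [ranger::ranger()]) on weekday and hour of day
#' plus the other channels' current values, and its missing entries are
#' re-predicted. Iteration stops early when the change between successive
#' imputations stops decreasing, returning the previous round's values.
#' Forests use `n_trees` trees and `floor(sqrt(p))` candidate variables per
#' split.
#'
#' @param target A `participant_series`.
#' @param n_trees Trees per forest (default 100).
#' @param max_iter Maximum imputation rounds (default 5).
#' @param seed Integer seed; required.
#' @param channels Channels to impute (default all three).
#' @return A `wear_imputation` with one completed dataset.
#' @export
impute_random_forest <- function(target, n_trees = 100L, max_iter = 5L,
                                 seed, channels = CHANNELS) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  set.seed(seed)
  ca <- channel_args(target)
  mis <- lapply(target[CHANNELS], is.na)
  active <- channels[vapply(channels, function(ch) any(mis[[ch]]), TRUE)]
  cur <- as.data.frame(target[CHANNELS])
  for (ch in names(cur)) {
    if (all(is.na(cur[[ch]]))) stop("channel ", ch, " has no observed minutes")
    cur[[ch]][mis[[ch]]] <- mean(cur[[ch]], na.rm = TRUE)
  }
  if (length(active) > 0L) {
    df <- cbind(cur, wd = ca$wd, hf = ca$hf)
    prev_diff <- Inf
    for (it in seq_len(max_iter)) {
      old <- cur
      for (ch in active) {
        preds <- c("wd", "hf", setdiff(CHANNELS, ch))
        df[CHANNELS] <- cur
        train <- df[!mis[[ch]], c(ch, preds)]
        fit <- ranger::ranger(
          stats::as.formula(paste(ch, "~ .")), data = train,
          num.trees = n_trees, mtry = floor(sqrt(length(preds))),
          seed = sample.int(.Machine$integer.max - 1L, 1L),
          num.threads = 1L
        )
        cur[[ch]][mis[[ch]]] <-
          stats::predict(fit, df[mis[[ch]], preds, drop = FALSE],
                         num.threads = 1L)$predictions
      }
      dd <- sum(vapply(active, function(ch)
        sum((cur[[ch]] - old[[ch]])^2) / sum(cur[[ch]]^2), 0))
      if (dd > prev_diff) {
        cur <- old
        break
      }
      prev_diff <- dd
    }
  }
  out <- target
  for (ch in channels) {
    out[[ch]][mis[[ch]]] <- clip_channel(cur[[ch]][mis[[ch]]], ch)
  }
  new_wear_imputation(list(out), "random_forest")
}
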