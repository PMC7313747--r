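---
title: "Wear-time scaling and imputation for activity-monitor data: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wear-time scaling and imputation for activity-monitor data: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette records the statistical model behind `wearimpute`, the design
decisions that were genuinely open, and what the package's synthetic
experiments can and cannot say about real data.

## The data model

The unit of analysis is a minute-resolution multichannel series per
participant: steps/min, heart rate (bpm) and energy (kcal/min) on a complete,
strictly increasing 1-minute grid starting at midnight. Missingness is
channel absence, never a missing row, and a minute without a heart-rate
reading is *non-wear*: wrist-worn monitors transmit no pulse signal when off
the wrist, so heart-rate absence is the wear-time oracle, and all channels of
a non-worn minute are treated as missing downstream even if the file carries
values for them. Timestamps are timezone-naive local clock time; a weekend
day is a Saturday or Sunday of the timestamp's calendar date.

## Wear-time scaling

The scaling algorithm rests on one empirical fact about these series:
autocorrelation is strongly local. Minute-level heart rate keeps ACF around
0.5-0.6 within 15-30 minutes while steps decay faster, and next-day
periodicity is an order of magnitude weaker than short-lag correlation. Data
adjacent in time are therefore the best available surrogate for a short gap,
and dividing a partial-wear sum by the wear proportion — equivalent to
imputing each missing minute with the mean of its observed neighbours inside
the same hour — is both cheap and nearly unbiased whenever activity is
roughly uniform at the hour scale.

Three validity thresholds guard the extrapolation: at least 5 worn minutes
per hour, 18 valid hours per day, and 4 valid days (including one weekend
day) per fortnight. The hour and day thresholds correspond to the points
where agreement (two-way mixed-effects absolute-agreement ICC, single
measure) between degraded and true data stays above 0.9 in the package's own
`wear_requirement_curve()` experiments; the day criterion is deliberately
conservative so that morning, afternoon and evening are all represented, and
the weekend-day rule protects the fortnight mean from weekday/weekend
behavioural differences.

One step of the cascade is ambiguous in prose: whether daily totals sum raw
or scaled hourly totals. The package sums *scaled* hourly totals and gives
wear credit only to valid hours, because that is the reading under which the
two scalings compose — a day of fully-worn hours and a day of uniformly
half-worn hours then yield identical expectations. Invalid hours contribute
neither value nor wear credit. Heart rate itself is never scaled: scaling
applies to accumulable quantities only, and intensity categories are scaled
through their per-minute 0/1 indicators, which makes the four scaled
category-minute totals sum exactly to 60 per valid hour and 1440 per valid
day.

## Intensity classification

Relative intensity is the heart-rate-reserve position
`%HRR = (HR - HRrest)/(HRmax - HRrest) * 100`, with `HRmax = 208 - 0.7 age`
and `HRrest = 1.08 HRsleep`. Sleeping heart rate is the minimum
20-consecutive-minute mean between 00:00 and 07:59 with fewer than 5
steps/min throughout, pooled over all nights of the series (the per-night
versus per-participant choice is not fixed by the definition; pooling gives a
single stable anchor and is what the package does). Windows containing any
missing heart-rate minute are skipped, and a window cannot straddle
07:59-08:00. When no qualifying window exists — shift workers, aggressive
non-wear at night — the estimator refuses rather than guessing; a resting
rate can then be supplied directly to `intensity_profile()`.

The printed category boundaries overlap at 20/40/60; the package adopts
half-open-on-the-left intervals (sedentary < 20, light [20, 40), moderate
[40, 60), vigorous >= 60), so every finite %HRR maps to exactly one category.

## Imputation comparators

*Mean imputation* fills with the plain observed mean, either the
participant's own or pooled over the cohort.

*Multiple imputation* uses bootstrap predictive mean matching: per
imputation, a bootstrap resample of observed minutes is fitted with a linear
main-effects predictor (weekday, plus hour-of-day in individual scope; age
and sex additionally in the pooled cohort scope), and each missing minute
copies a random one of the `k = 5` observed donors with nearest predictions.
Defaults are `m = 5` imputations cohort-wide and `m = 7` individually. These
internals are a documented dialect of the method class, not a reproduction of
any specific package. Two numerical details matter. First, coarse categorical
predictors produce large blocks of exactly tied predictions; donors are
therefore ranked with a random tie-break (a jitter about nine orders of
magnitude below any real prediction difference), so each missing minute draws
from its whole tie block rather than a fixed corner of it. Second, point
estimates downstream average the `m` completed-dataset summaries; pooling
rules for variances are out of scope because only point errors and means are
evaluated.

*Kalman imputation* fits, per channel, a Gaussian local-level structural
model (random-walk level variance `q`, observation variance `r`) by maximum
likelihood (`stats::StructTS`), runs the Kalman smoother across the full
grid with missing minutes as absent observations, and fills with the
smoothed level. The local-level form (no trend or seasonal component) was
chosen because short-lag correlation dominates these series; a daily
seasonal at period 1440 would multiply state dimension for little gain at
gap lengths of at most two hours. A channel whose observed values are
constant is filled with that constant — the degenerate `q, r -> 0` limit,
taken directly rather than through an ill-conditioned optimisation. Fitted
fills agree with exact Gaussian conditioning at the same `(q, r)` to below
`1e-4` in the test suite.

*Random forest imputation* is the iterative chained scheme: initialise with
channel means, then repeatedly regress each channel on weekday, hour and the
other channels' current values (100 trees, `floor(sqrt(p))` variables per
split) and re-predict the missing entries, stopping early when the change
between successive imputations stops decreasing and returning the previous
iterate.

Imputed steps and energy are clipped below at zero and imputed heart rate to
(25, 250) bpm; observed minutes are never altered by any method.

## Evaluation statistics

RMSE is `sqrt(mean((predicted - true)^2))`, pooled over participant-hours,
participant-days, or participants (one 14-day value each) depending on the
level; units the scaling algorithm removes are excluded pairwise for that
method only. Equivalence uses the paired two-one-sided-tests form: the
criterion "90% CI of the difference within +/- 10% of the criterion mean" is
exactly the TOST rejection region at one-sided alpha 0.05, and both views are
reported (`p_lower`, `p_upper`, and the CI). Zero-variance differences get
the degenerate verdict `|mean d| < bound` with p-values of 0/1. The agreement
ICC is computed from the closed-form two-way ANOVA decomposition; a
zero-variance table is an error, not a silent 0 or 1.

## The synthetic cohort

Real trial data cannot be redistributed, so the package carries a generative
stand-in used by all experiments. Per participant: a fixed nightly sleep
window (default 23:00-07:00) with zero steps and quiet heart rate
(`N(HRsleep, 2.5 bpm)`); waking "fidget" steps `Poisson(2)` per minute;
activity bouts from a Poisson process with uniform lengths (10-40 min) and
cadences (50-110 steps/min); heart rate
`HRrest + 0.9 * (cadence/180) * (HRmax - HRrest)` plus AR(1) noise
(coefficient 0.8, marginal SD 7 bpm), clipped to (25, 250); and energy
`basal * (1 + 4 * steps/180)` kcal/min. Quiet waking minutes additionally sit
16 bpm above rest: without that term a cadence-coupled model produces almost
no light-intensity time, because sitting and strolling both collapse onto
the resting rate. The bout rate is solved from the daily step target through
a Poisson-coverage equation, which compensates for overlapping bouts.

Population defaults (age ~ N(47.5, 9.6) truncated to [22, 75], 85% female,
step targets ~ N(10570, 3209), basal ~ N(1.55, 0.15) kcal/min) were set so
that simulated cohort means — roughly 10,400 steps/day, 2,590 kcal/day, and
1,100/280/53/5 sedentary/light/moderate/vigorous minutes/day — fall inside
the ranges reported for free-living middle-aged cohorts wearing these
devices. The AR(1) coefficient reproduces the qualitative short-lag ACF
ordering (heart rate well above steps).

What the generator does *not* emulate: physiological energy dynamics (VO2
kinetics, EPOC), weekday/weekend behavioural differences, informative
(behaviour-dependent) non-wear, device quantisation and drift, and
between-day habit structure. Passing simulations therefore demonstrate
correctness of the algorithms under a plausible circadian signal with
missing-completely-at-random gaps — not performance guarantees under
informative missingness, which no simulation of this kind can establish.

## Missingness simulation

Gap insertion mirrors observed non-wear: independent periods with uniform
random starts and integer lengths uniform on 1-120 minutes, truncated at the
series end and applied as a union (the simplest reading of independent random
insertion; overlaps are allowed). Forty periods mark about 11.3% of a
fortnight missing on average, with a hard per-series ceiling of 23.8%. The
incremental design runs ten windows whose period counts are uniform on
{10(w-1), ..., 10w}, reaching roughly 28% inserted missingness in window ten.

## Problem sizes and numerical conventions

The shipped experiments are sized for a single CPU: the cohort-level
qualitative checks run 30 synthetic participants through the fixed-missing
design (random forests at 25 trees and 2 iterations there; the all-methods
beat-removal comparison is insensitive to forest size) and 6 participants
through windows 1 and 10 of the incremental design with 3 simulations per
window. Monotone-trend claims are tested with a paired sign test rather than
strict per-window ordering, since Monte-Carlo noise can reorder adjacent
windows. Seeds are mandatory everywhere randomness occurs — generators,
plans, imputers and drivers refuse to run without one — and all sub-streams
derive deterministically from a single root seed. CSV round-trips write full
`%.17g` precision so that write-then-read is bit-exact, with missing values
as empty cells rather than sentinels.

## Known limitations

The scaling algorithm extrapolates within-hour means; a gap covering an
entire exercise bout is unrecoverable by any within-participant method, and
gaps adjacent to bouts bias moderate/vigorous minutes upward slightly. The
pooled-cohort multiple imputation model conditions only on age, sex and
weekday, so its fills are close to stratified random draws; it exists as a
comparator, not a recommendation. The equivalence margin (10% of the
criterion mean) is a convention inherited from the agreement literature, not
a clinically derived bound.
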