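# wearimpute

Commercial wrist-worn activity monitors report minute-level steps, heart rate
and energy expenditure, but only while they are worn. Because non-wear minutes
simply vanish from the record (no heart-rate reading is transmitted when the
device is off the wrist), naive daily or weekly summaries silently treat every
missing minute as zero activity and systematically underestimate physical
activity. `wearimpute` provides the tools a physical-activity researcher needs
to deal with this: a wear-time scaling algorithm with minimum-wear validity
thresholds, the standard imputation alternatives to compare it against, and
the evaluation machinery (RMSE, equivalence testing, agreement ICC,
autocorrelation) to decide which approach is adequate for a given metric.

## The scaling algorithm

Let a minute be *worn* when a heart-rate reading is present. For each clock
hour with observed total `x` over `n` worn minutes:

- if `n < 5`, the hour is removed (invalid);
- otherwise the scaled hourly total is `x / (n/60)`.

For each day with `h` valid hours summing (scaled) to `X`:

- if `h < 18`, the day is removed;
- otherwise the scaled daily total is `X / (h/24)`.

A 14-day summary is the mean over valid days, and is itself removed when
fewer than 4 days — or no Saturday/Sunday — survive. The same machinery
applies to steps, energy (TDEE) and minutes in heart-rate-reserve intensity
categories, where the per-minute summand is a category indicator derived from

```
%HRR = (HR - HRrest) / (HRmax - HRrest) * 100
```

with `HRmax = 208 - 0.7 * age` (Tanaka), `HRrest = 1.08 * HRsleep`, and
`HRsleep` the lowest 20-consecutive-minute night-time mean. Cut points:
sedentary < 20%, light [20, 40), moderate [40, 60), vigorous >= 60%.

Comparators implemented behind the same interface: cohort/individual mean
imputation, bootstrap predictive-mean-matching multiple imputation (m = 5
cohort-wide, m = 7 individual), Kalman smoothing under a maximum-likelihood
local-level structural model, iterative random forest imputation, and plain
removal. A synthetic-cohort generator (circadian sleep window, Poisson
activity bouts, HR coupled to cadence) makes every experiment runnable
without access to trial data.

## Worked example

```r
library(wearimpute)

series <- generate_participant(participant_profile(age = 52, target_daily_steps = 9000),
                               seed = 2024, participant_id = "P001")
plan   <- draw_plan(n_periods = 40, series_length = nrow(series), seed = 99)
masked <- apply_plan(series, plan)$masked
masked
#> <participant_series> P001 (female, age 52)
#>   20160 minutes from 2020-01-06 00:00 to 2020-01-19 23:59
#>   wear time: 17630/20160 minutes (87.5%)

removal_summary(series, "steps", "period")$value   # truth:   9389.0 steps/day
removal_summary(masked, "steps", "period")$value   # removal: 7601.4  (-19%)
nohow_summary(masked, "steps", "period")$value     # scaled:  9138.3  (-2.7%)
removal_summary(completed_series(impute_kalman(masked)),
                "steps", "period")$value           # Kalman:  9305.4  (-0.9%)
```

Dropping the 12.5% of minutes the inserted gaps removed costs almost a fifth
of the step count; wear-time scaling and Kalman imputation both recover the
truth to within a few percent. Intensity classification works the same way:

```r
prof <- intensity_profile(series)
prof
#> <intensity_profile> age 52.0: HRmax 171.6, HRsleep 53.2, HRrest 57.4 bpm
head(minutes_by_category(series, prof), 3)
#>         date sedentary light moderate vigorous
#> 1 2020-01-06      1203   208       28        1
#> 2 2020-01-07      1049   340       49        2
#> 3 2020-01-08      1139   285       16        0
```

Cohort-scale comparisons come from `run_study1()` (fixed missingness, all
methods on identical masked data) and `run_study2()` (ten incremental
missingness windows), both returning tidy tables of RMSE, mean differences
and TOST equivalence verdicts. `inst/cli/wearimpute.R` exposes the same
operations as shell subcommands (`simulate-cohort`, `insert-missingness`,
`impute`, `hrr`, `summarize`, `study1`, `study2`, `run`).

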