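# hvemsim

Monte-Carlo estimation of how long ambulatory **home video-EEG monitoring
(HVEM)** must run to capture 1, 3, or 5 epileptic seizures on distinct
calendar days, for pediatric and adult patients with 1–30 seizures per
month.

Unlike inpatient monitoring units, home monitoring cannot safely taper
anti-seizure medication, so seizure capture is governed entirely by each
patient's natural seizure frequency — and, in many adults, by multidien
(week-to-month scale) seizure cycles. `hvemsim` simulates large synthetic
cohorts (by default 50,000 children and 50,000 adults, one year of daily
seizure counts each), monitors every patient from a mid-year start day
until each goal is met, and reports the distribution of required durations.

## The model in brief

1. **Annual frequency.** Monthly frequency follows a point density on
   breakpoints 1–10 (step 1) and 10–30 (step 5). Interval *i* gets weight
   `mPD*_i = (PD_is + PD_ie)/2`, probability `P_i = mPD*_i · L_i`,
   normalized to `nP_i = P_i / Σ P`. A patient in interval *i* draws an
   integer annual total uniformly on `[12·start_i, 12·end_i]`.
2. **Daily placement.** Non-cycling courses place each seizure on a uniform
   random day of the year. Cycling courses (60% of adults; periods
   7/15/20/30 d at 20/17/30/33%; children never cycle) lock a fraction
   `f ~ N(0.34, 0.18)` (clipped to [0, 1]) of seizures to the active
   half-cycle days — ones-first binary templates, all starting day 1 —
   and spread the rest uniformly.
3. **Monitoring.** Start day is uniform on days 151–210 (or Gaussian around
   day 180, SD ≈ 1 day, to synchronize with cycle onsets). Monitoring stops
   at the k-th distinct seizure day; the duration is the number of days
   elapsed from the start day, extending the course in-phase past day 365
   when needed.
4. **Reporting.** Mean/SD/median/IQR/skewness per cohort and goal, pooled
   two-sample t-tests between groups, and weekly capture percentages
   (weeks 1–10).

When the original digitized density grid is unavailable,
`calibrate_surrogate_grid()` deterministically fits a truncated-lognormal
surrogate whose induced monthly distribution matches the published summary
statistics (children mean 9.64, median 7.08, SD 7.61; adults 8.30 / 5.50 /
7.22 seizures/month). Pre-calibrated surrogate grids ship in
`inst/extdata/`.

## Worked example

```r
library(hvemsim)

grid <- calibrate_surrogate_grid(surrogate_spec("children"))
tab  <- build_interval_table(grid)
head(as.data.frame(tab), 3)
#>   start end length mean_density   prob norm_prob
#> 1     1   2      1       0.0813 0.0813    0.1210
#> 2     2   3      1       0.0677 0.0677    0.1007
#> 3     3   4      1       0.0565 0.0565    0.0841

set.seed(42)
summarize_monthly(sample_annual_counts(tab, 10000))
#>   mean median   sd
#> 1 9.54   7.08 7.49
```

The interval probabilities `norm_prob` say, e.g., that 12.1% of included
children have 1–2 seizures/month; a 10,000-patient draw reproduces the
published monthly moments. A single cycling patient:

```r
tc <- generate_cycling_timecourse(120, build_cycle_template(20, 365))
tc
#> <timecourse> 120 seizures/year over 365 days; 20-day cycle, phase-locked fraction 0.349

monitor_until_goal(tc, start_day = 180, goal = c(1, 3, 5))
#> [1]  2  7 18
```

This patient's first seizure day fell 2 days after setup; the third and
fifth distinct seizure days needed 7 and 18 days. A full (here scaled-down)
study:

```r
res <- run_study(hvem_config(n_children = 5000, n_adults = 5000, seed = 1))
res$table1[res$table1$comparison == "adults vs children (random start)",
           c("goal", "mean_a", "median_a", "sd_a", "mean_b", "median_b", "sd_b", "p_value")]
#>   goal mean_a median_a  sd_a mean_b median_b  sd_b   p_value
#> 1    1  7.585        3 12.19  6.101        2 10.82 1.241e-10
#> 2    3 25.052       15 26.62 19.834       11 22.61 5.967e-26
#> 3    5 41.878       27 40.22 34.083       21 34.88 5.462e-25

subset(res$fig1, age_group == "children" & goal == 1 & week <= 3)
#>   age_group goal week percent_captured
#> 1  children    1    1            73.88
#> 2  children    1    2            87.20
#> 3  children    1    3            93.16
```

Columns `_a` are adults, `_b` children: adults need significantly longer
monitoring for every goal (e.g. a median of 27 vs 21 days beyond setup for
five seizure days), and about 74% of children have their first seizure
captured within one week of recording. `run_study(cfg, out_dir = ...)`
additionally writes the comparison table, weekly capture grid, per-patient
duration CSVs, annual-count histograms, and a `run_metadata.json` with the
seed and config hash. `scripts/run_study.R` wraps this for shell use.

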