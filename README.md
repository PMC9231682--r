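# calanmeals

Feeding-behavior analysis for dairy cows at gated feed bunks (Calan
Broadbent systems), from door-mounted 3-axis accelerometer logs.

Each Calan gate door carries a pendant logger that records static
acceleration; the tilt of its Z axis (`tilt = 180° − arccos(a)`, `a` in g)
tracks the door: ~0° closed, >60° fully open. Thresholding tilt at 30°
yields a binary open/closed series per cow at a fixed epoch (30 s).
`calanmeals` turns those series into meals:

1. run-length encode door states into open bouts and closed gaps;
2. drop gaps under 2 min and fit Gaussian mixtures to
   `x = log(gap in seconds)`,
   `p(x) = Σ_k π_k N(x; μ_k, σ_k²)`, comparing K = 2 vs 3 by AICc/BIC
   (`k = 3K − 1` free parameters);
3. set the **minimum intermeal interval** (MII, the meal criterion) at the
   intersection `C` of the two rightmost component densities —
   `N(C; μ₁, σ₁) = N(C; μ₂, σ₂)`, solved by the log-density quadratic —
   so the criterion in minutes is `exp(C)/60`;
4. merge open bouts separated by gaps shorter than the MII into meals,
   drop single-epoch door touches, and summarize meal frequency and length
   per cow-day.

It also validates sensor calls against a human observer (2×2 contingency,
Cohen's κ with 95% CI, PPV/NPV), plans logger missions
(`fill time = (memory − header)/(rate × axes)`), and ships a seeded
synthetic-data generator with ground truth for every stage.

## Worked example

Simulate a small herd and run the full pipeline:

```r
library(calanmeals)

cfg    <- sim_config(n_cows = 6, n_days = 3, seed = 42)
bundle <- simulate_feeding_study(cfg)
report <- run_feeding_pipeline(bundle$tilt[, c("cow_id", "timestamp", "tilt_deg")])
report
#> Feeding-behavior pipeline report
#> # A tibble: 8 × 2
#>   stage                        n
#>   <chr>                    <int>
#> 1 samples                  51840
#> 2 open_bouts                1079
#> 3 raw_intervals             1061
#> 4 intervals_excluded_short   600
#> 5 intervals_fitted           461
#> 6 meals_assembled            150
#> 7 meals_removed_short          0
#> 8 meals_kept                 150
#> Selected mixture: K = 3 (BIC rule)
#> Meal criterion: C = 7.394 log-s  =>  minimum intermeal interval 27.1 min
#> Meals: 8.3 +/- 1.7 per day; length 60.2 +/- 58.7 min

bundle$planted_criterion$mii_minutes   # truth the generator planted
#> [1] 31.37967
```

Reading the output: 51,840 tilt samples collapse to 1,079 door-open bouts;
600 of 1,061 closed gaps fall under the 2-min filter (the within-meal pause
regime); the 3-component mixture wins on BIC and its two rightmost
components intersect at `C = 7.39` log-seconds, i.e. a 27.1-min meal
criterion against a planted 31.4 min — about what three cow-weeks of data
buy; recovery tightens with herd size. Merging bouts at that criterion
gives 8.3 meals/day.

The criterion from published component parameters directly:

```r
meal_criterion_from_params(6.34, 0.61, 8.77, 0.63)
#> Meal criterion: C = 7.541 log-s  =>  minimum intermeal interval 31.4 min
```

`tidy()`/`glance()` give component and model tables, `autoplot()` draws the
fitted mixture over the interval histogram, and `inst/cli/calanmeals` is a
thin command-line front end (`simulate`, `run`, `validate`, `plan`).

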