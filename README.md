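# ecohortr

Adherence, scoring, and app-versus-clinic agreement analysis for
smartphone-survey eCohorts.

Digital cohort studies ("eCohorts") embedded in traditional clinic-based
cohorts collect repeated health surveys through a smartphone app over many
months. Three questions dominate the methodology of such studies, and this
package implements a complete, tested pipeline for all three:

1. **Engagement.** When a survey can be returned at any time, which protocol
   wave does a given return belong to, and what fraction of participants is
   still returning (and completing) surveys at each wave?
2. **Validity.** Do app-reported measures agree with the same instruments
   administered at a research-center examination?
3. **Stability.** Do repeated app measures drift across waves?

The package is tidyverse-native: every analysis function takes a data frame
and returns a tibble, fitted objects have `tidy()`/`glance()` methods, and
result types have ggplot2 plot functions. Because participant-level data
from real eCohorts are typically not public, the package ships a synthetic
cohort generator (`simulate_cohort()`) that reproduces the statistical
structure the pipeline assumes, so every stage is exercised end to end by
code alone.

## The methods in brief

* **Time windows.** A return on day *d* after registration (whole days,
  floored) maps to baseline for *d* ∈ [0, 89], and to the 3-, 6-, 9- and
  12-month waves for [90, 179], [180, 269], [270, 359], [360, 449];
  later returns are excluded. Participants with under 12 months of
  follow-up, or whose first return falls on day 90 or later, are excluded
  from adherence denominators; non-returners are retained.
* **Adherence.** A survey counts as completed when at least 75% of its
  items were answered. Two per-wave metrics share one post-exclusion
  denominator: the proportion completing **at least one** survey, and the
  proportion completing **all** scheduled surveys.
* **Scoring.** Physical Activity Index
  `PAI = 1·sleep + 1.1·sedentary + 1.5·slight + 2.4·moderate + 5·heavy`
  (daily hours summing to 24; a single missing category is imputed as
  `24 − Σ others`). CES-D = sum of 20 items in 0–3 (1–5 missing items:
  mean × 20; more than 5: missing; depression flag at ≥ 16). Weekly
  alcohol = drinks/day × drinking days/week.
* **Agreement.** Lin's concordance correlation coefficient
  `ρ̂_c = 2s_xy / (s_x² + s_y² + (x̄ − ȳ)²)` with a Fisher-z confidence
  interval, unweighted Cohen's κ with its asymptotic standard error, and
  Bland-Altman bias with `bias ± 1.96·SD` limits of agreement, all against
  the clinic measurement as gold standard.
* **Trends.** Balanced-panel random-intercept model
  `y_it = μ + β_wave + b_i + e_it` (closed form: wave effects are wave-mean
  differences; variance components from the within/between mean squares),
  and a paired t test for the two-wave alcohol comparison.

## Worked example

```r
library(ecohortr)

report <- run_pipeline(cohort_config(n_participants = 2000, seed = 42),
                       quiet = TRUE)
report$adherence
#> # A tibble: 5 × 8
#>   wave     n_any n_all denominator p_any  p_all pct_any pct_all
#>   <chr>    <int> <int>       <int> <dbl>  <dbl>   <dbl>   <dbl>
#> 1 baseline  1786  1390        1965 0.909 0.707     90.9   70.7
#> 2 m3        1039  1039        1965 0.529 0.529     52.9   52.9
#> 3 m6         919   702        1965 0.468 0.357     46.8   35.7
#> 4 m9         701   701        1965 0.357 0.357     35.7   35.7
#> 5 m12        686    24        1965 0.349 0.0122    34.9    1.22
```

Of 2000 simulated enrollees, 1965 survive the eligibility rules (the
denominator for every wave). Engagement starts high — 90.9% complete at
least one baseline survey — and declines to about 35% at 12 months; the
all-surveys metric collapses to 1.2% at 12 months because almost nobody
returns the final medical-history update, while the single-survey waves
(3 and 9 months) show identical values for both metrics by construction.

```r
dplyr::filter(report$agreement, statistic %in% c("ccc", "kappa"))
#> # A tibble: 4 × 7
#>   measure         n_dropped statistic estimate ci_low ci_high n_pairs
#>   <chr>               <int> <chr>        <dbl>  <dbl>   <dbl>   <int>
#> 1 pai                   252 ccc          0.566  0.536   0.594    1748
#> 2 cesd_sum              253 ccc          0.768  0.748   0.786    1747
#> 3 drinks_per_week       266 ccc          0.819  0.803   0.834    1734
#> 4 depression_flag       253 kappa        0.548  0.491   0.605    1747
```

App-versus-clinic concordance is moderate for physical activity (0.57) and
high for depressive symptoms (0.77) and weekly drinks (0.82) — these are
the generator's calibrated operating points, recovered by the estimators
from the simulated item responses. `n_dropped` counts incomplete pairs
removed by the complete-case rule.

```r
report$returner_model
#> # A tibble: 7 × 5
#>   term             aOR ci_low ci_high         p
#> 1 age            1.01  0.988    1.02  0.530
#> 2 female         1.99  1.46     2.72  0.0000159
#> 3 current_smoker 0.516 0.311    0.858 0.0107
#> ...
```

Women have higher adjusted odds of returning surveys and current smokers
lower, matching the generating log-odds effects.

Individual stages are ordinary functions on data frames — e.g.
`assign_waves()`, `survey_adherence()`, `score_pai()`, `ccc()`,
`bland_altman()` (with an `autoplot()` method), `fit_random_intercept()` —
see the methods vignette (`vignettes/ecohort-methods.Rmd`) for the full
model description.

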