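# chronodiet

Diet-quality and meal-timing analysis for two-recall dietary surveys.

Many national nutrition surveys collect two non-consecutive 24-hour
dietary recalls per subject, each day a short list of timed eating
occasions (up to eight labelled slots from "before breakfast" to "after
dinner snack") with database-resolved energy and nutrient content.
chronodiet implements the full analysis pipeline for such data, for
nutrition epidemiologists who want the standard descriptive tables, a
compact diet-quality index, and chrononutrition metrics from one package:

* **Intake summaries** — per-day totals and two-day-averaged subject
  summaries with derived metrics: percent of energy from macronutrients
  via Atwater factors (4/4/9/7 kcal per g of carbohydrate / protein / fat
  / alcohol), fiber density (g/1000 kcal), energy density (kcal/g food),
  protein per kg body weight.
* **Meal timing** — percent of energy consumed before a clock cutoff
  (default 16:00, pooled over both days), early-eater classification
  (≥ 60% of energy before the cutoff), eating after 20:00 (any occasion
  starting strictly later, either day), largest-meal identification and
  timing, between-day lunch consistency.
* **Diet Quality Score (DQS)** — one point per recommendation met:
  fruit + vegetables ≥ 400 g/day, fiber ≥ 14 g/1000 kcal, sugar < 10% of
  energy, saturated fat < 10% of energy, sodium < 2.3 g/day; score 0–5
  with ordinal categories 0–1 / 2–3 / 4–5. Its continuous companion, the
  diet-quality z-score, is the sum over components of
  `sign * (intake − recommendation) / cohort SD`, signs +1 for
  fruit/vegetables and fiber, −1 for sugar, saturated fat and sodium.
* **Statistics** — tidy wrappers for two-sample t-tests (Welch or
  pooled), Pearson chi-square, Benjamini–Hochberg FDR (step-up), Spearman
  correlation, one-way ANOVA with Tukey HSD, OLS regression, and a
  REML random-intercept mixed model of per-meal energy
  (`kcal ~ meal + (1 | subject)`) with marginal means and Wald contrasts.
* **Synthetic cohorts** — a generator that emulates the statistical
  structure of a Serbian-style national survey (74 children + 260 adults,
  lunch around 15:15 as the largest meal, adult energy 2265 ± 987 kcal,
  and a latent "traditionalism" factor coupling earlier eating with higher
  fruit/vegetable intake and lower energy), so the entire pipeline runs
  and is testable without access to survey data.
* **Report building** — `run_pipeline()` assembles the survey-style
  tables (nutrient summary with child-vs-adult tests and FDR, early/late
  and after-20:00 comparisons, per-occasion summary, histogram data by DQS
  category, DQS-category ANOVAs) plus ggplot2 views.

## Worked example

```r
library(chronodiet)
library(dplyr)

# a synthetic survey: 74 children, 260 adults, two recall days each
cohort <- generate_cohort(synthetic_config(seed = 1))
report <- run_pipeline(cohort$recalls, cohort$subjects)
report
#> Diet-quality and meal-timing survey report
#>   subjects: 334 ( 260 adults )
#>   adult DQS mean: 1.69 | z-score mean: -2.13
#>   early eaters: 138 of 260

# two-day averaged intakes and derived metrics
subject_intake(cohort$recalls, cohort$subjects) |>
  select(subject_id, energy, fiber_density, fruit_veg, pct_energy_before_cutoff) |>
  head(3)
#>   subject_id energy fiber_density fruit_veg pct_energy_before_cutoff
#> 1 S0001       1684.          6.59      293.                     64.5
#> 2 S0002       2662.          5.49     1088.                     46.7
#> 3 S0003       4128.          2.12      286.                     58.8

# adult diet-quality scoring
count(report$adult_dqs, dqs_category)
#> 1 0-1            115
#> 2 2-3            129
#> 3 4-5             16

# the early-vs-late comparison (fruit+veg row): early eaters average
# 515 g/day against 399 g/day for late eaters on this draw
report$table_early_late$continuous |>
  filter(variable == "fruit_veg") |>
  select(mean_a, mean_b, p_value, significant)
#>   mean_a mean_b  p_value  significant
#> 1   515.   399. 0.000719  TRUE

# mixed model of per-meal energy: lunch is the largest meal
meal_energy_long(cohort$recalls, cohort$subjects, adults_only = TRUE) |>
  meal_energy_model()
#> Random-intercept model of per-meal energy (kcal)
#>   breakfast     535.      19.0
#>   lunch         756.      19.0
#>   dinner        564.      19.0
#> variance components: between-subject 58303 , residual 70228

# adjusted trend of diet quality on early eating
report$z_regression$adjusted
#>   term                     estimate std_error statistic  p_value
#> 1 (Intercept)               -5.31     0.556       -9.54 1.21e-18
#> 2 pct_energy_before_cutoff   0.0234   0.00871      2.68 7.75e- 3
#> 3 age                        0.0234   0.00768      3.04 2.58e- 3
#> 4 femaleTRUE                 1.38     0.262        5.28 2.78e- 7
```

On this draw the early eaters (at least 60% of daily energy before 16:00)
consume about 116 g/day more fruit and vegetables than late eaters, and
the adjusted regression of the diet-quality z-score on percent of energy
before 16:00 estimates a slope of 0.023 (SE 0.009) per percentage point;
averaged over many regenerated cohorts the estimates center on the
generative values (a 96 g/day gap and a slope of 0.03) — the structure the
generator builds in, and the pattern the pipeline is designed to measure
in real recall data.

Figures: `autoplot(report)` (per-occasion energy profile),
`plot_largest_meal_hist(report)` and `plot_pct_before_hist(report)`
(timing histograms stratified by DQS category).

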