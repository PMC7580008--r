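---
title: "Diet quality and meal timing from two-recall surveys: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diet quality and meal timing from two-recall surveys: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronodiet)
library(dplyr)
```

chronodiet analyses nutrient-resolved 24-hour dietary recall surveys in
which every subject contributes two recall days, each day a short list of
timed eating occasions. This vignette explains the models and conventions
the package implements, the tunable parameters and their defaults, what the
synthetic-cohort generator does and does not emulate, and the numerical
choices a maintainer should know about.

## Data model

A recall table has one row per (subject, day, eating occasion). Occasions
are drawn from eight labelled slots (`occasion_labels()`): before
breakfast, breakfast, morning snack, lunch, up to two afternoon snacks,
dinner and an after-dinner snack. Only the *start* of an occasion is
recorded, as integer minutes since midnight in `[0, 1439]`; no duration is
modelled, and occasions are assumed to lie within one calendar day (the
slot list ends at the after-dinner snack, so a post-midnight wrap has no
representation). Each occasion carries energy (kcal) and amounts of
carbohydrate, protein, fat, saturated fat, sugar, fiber, sodium, fruit,
vegetables, alcohol and food mass in grams, and water in millilitres. All
quantities must be non-negative, a label may appear at most once per day,
and a day holds one to eight occasions.

Ages are accepted as non-integers; the five survey age categories (10-17,
three adult tertiles with default bounds 18-29 / 30-47 / 48-64, and 65-74)
use half-open intervals on integer-year labels, so 17.9 is still a child
and 18.0 an adult. Missing anthropometry is tolerated everywhere:
BMI-dependent outputs exclude such subjects instead of failing.

## Intake metrics

Per-day totals are plain sums over occasions. The subject-level summary
averages the two days first and derives every ratio from the averaged
numerator and denominator (ratio of means, not mean of ratios):

* percent of energy from a macronutrient is
  $100 \cdot g \cdot f / E$ with the conventional Atwater factors
  $f$ = 4 (carbohydrate), 4 (protein), 9 (fat), 7 (alcohol) kcal/g;
  saturated fat uses the fat factor and sugar the carbohydrate factor.
  The denominator $E$ is the *reported* (food-database-derived) energy, not
  a value recomputed from macronutrients, so the percentages need not sum
  to 100 on real data. On synthetic data, whose energy is consistent with
  Atwater arithmetic by construction, they sum to 100 exactly;
* fiber density is $1000 \cdot \text{fiber} / E$ g/1000 kcal;
* energy density is $E / \text{food mass}$, where food mass excludes
  drinking water and beverages. This exclusion is a documented assumption:
  an adult energy density near 0.9 kcal/g is arithmetically incompatible
  with a denominator that includes roughly three litres of daily fluids;
* protein per kg body weight needs a subject weight and is `NA` otherwise.

## Meal-timing metrics

"Consumed before 16:00" means the occasion *starts* strictly before the
cutoff (only start times exist). The percent of energy before the cutoff
pools both days — energy before the cutoff over total energy, which equals
average-kcal-before divided by average daily energy. A per-day-averaged
variant is available (`method = "per_day"`) because the two definitions
differ on unbalanced days; pooled is the default. The early-eater flag is
inclusive: at least 60% of energy before 16:00. The late-eating flag is
the strictest observable two-day version: any occasion starting strictly
after 20:00 on either day. The largest meal of a day is the occasion (meal
or snack) with maximal energy, ties broken by the earliest start; the
reported largest-meal time is the mean of the two per-day times even when
the winning occasion differs between days. Lunch consistency is the
absolute between-day difference in lunch start, with an inclusive
within-one-hour flag. All thresholds live in `timing_thresholds()`
(defaults: cutoff 960 min = 16:00, 60%, late 1200 min = 20:00).

## Diet Quality Score

The DQS counts how many of five EU Science Hub-style recommendations a
subject meets: fruit and vegetables at least 400 g/day, fiber at least
14 g/1000 kcal, sugar below 10% of energy, saturated fat below 10% of
energy, sodium below 2.3 g/day. Minima are inclusive and limits strict;
the operators are configurable (`strict_limits = FALSE`) because survey
reports are not always consistent about "less than" versus "or less" for
sodium — the package defaults to strict, following the methods-level
definition. Two caveats are deliberate: the sugar criterion is scored on
*total* sugar because that is the variable a recall survey produces, while
the underlying recommendation concerns added sugar; whole grains, protein
and water are not scored. A missing component value makes the score an
error naming the component — a partial DQS would not be comparable across
subjects.

The continuous companion is the diet-quality z-score
$z_{ij} = s_i (x_{ij} - r_i) / \mathrm{SD}_i$, with sign $s_i = +1$ for
fruit/vegetables and fiber and $-1$ for sugar, saturated fat and sodium,
and $\mathrm{SD}_i$ the sample SD (n-1) of the component over the cohort
passed in. The cohort is an explicit argument — the package computes
adult-only SDs when given the adult table, which is the intended use
because the score is defined for adults. The z-total is the sum of the
five components. Note the asymmetry the tests assert: the DQS of a subject
is invariant to the rest of the cohort, the z-score is not.

## Statistical engine

The comparison machinery wraps the standard R implementations behind a
tidy, tibble-first surface: Welch (default) or pooled two-sample t-tests,
Pearson chi-square without continuity correction, Spearman correlation
with average ranks and a t-approximation p-value (appropriate with ties),
one-way ANOVA with Tukey HSD (the studentized-range distribution, exact in
R via `ptukey`, with Tukey-Kramer SEs under unequal n), OLS with
rank-deficiency detection that names collinear columns, and
Benjamini-Hochberg FDR via the step-up-equivalent adjusted p-values.
The per-meal energy model is a REML random-intercept fit
(`lme4::lmer(kcal ~ 0 + meal + (1 | subject))`): cell-means coding makes
the fixed effects the per-meal marginal means; pairwise contrasts use Wald
z statistics because the reference analysis did not state a df convention
— on balanced data these agree with paired t-tests up to that convention,
which the tests check. Variance components are bounded below at zero by
the optimizer; singular fits are accepted (a zero between-subject
component is a legitimate estimate, which the tests exercise).

One reproducibility note: when re-analysing a published table of p-values
with BH, entries printed as "< 0.001" must be encoded as a number; the
package's convention is 0.0005. With that encoding, the early-vs-late
table's seventeen p-values yield exactly three discoveries at FDR 0.05
with the largest surviving raw p equal to 0.008. The analogous footnote of
the after-20:00 table (a cutoff of 0.036) is *not* reproducible by
standard step-up BH on its printed p-values — step-up yields a smaller
cutoff — and the package reproduces the procedure, not that footnote.

## Synthetic cohort

The generator emulates the statistical structure of a national two-recall
survey of 74 children and 260 adults (54% female; adult age categories
sampled in proportions 75/73/73/39 with uniform integer ages within each).
Its defaults are the study conditions, not dials:

* main meals are always present; snacks occur independently per day with
  probabilities 0.40/0.85/0.90/0.30/0.55 (before breakfast, morning, two
  afternoon slots, after dinner), giving six occasions per day on average;
* subject-level mean start times are normal around 9:00 (breakfast), 15:15
  (lunch) and 20:00 (dinner), with day-to-day jitter of about 20 minutes;
  the lunch jitter SD of 21 min/day makes the expected absolute
  between-day lunch gap $2\sigma/\sqrt{\pi} \approx 24$ minutes;
* occasion energies are lognormal around per-meal means of 537/761/568
  kcal for adults and 560/665/520 kcal for children — lunch is the largest
  meal in expectation — multiplied by a lognormal subject "appetite" scale
  whose CV (0.39) brings the daily-energy CV to the observed 0.44. Snack
  means are set so that expected daily energy is 2265 kcal for adults and
  2280 kcal for children;
* subject-level nutrient marginals target the adult survey means/SDs
  (fruit+vegetables 473/295 g, fiber density 10.9/6.4, sugar 13.2/7.4 %E,
  saturated fat 13/4 %E, sodium 3.99/3.00 g, water 2246/1333 ml, energy
  density 0.89/0.32 kcal/g) and the corresponding child values. Macronutrient
  percentages are drawn and normalized to sum to 100 with alcohol, then
  converted to grams through the Atwater factors, so the synthetic data are
  exactly Atwater-consistent. Fruit has a zero point mass (20% of adults,
  23% of children eat no fruit over the two days);
* a single latent "traditionalism" factor $T \sim N(0,1)$, loaded 0.45 on
  standardized age, induces the joint pattern the analysis looks for: an
  earlier lunch (-25 min per unit $T$), a relatively larger lunch and
  smaller dinner/late snack, and—through the realized percent of energy
  before 16:00—lower total energy, higher fruit/vegetable and fiber
  intake and slightly lower sugar, saturated fat and sodium. A single
  factor is the simplest structure that reproduces the reported correlated
  group differences without asserting a causal model;
* the headline couplings are expressed as the quantities the analysis
  estimates: `fv_gap = 96` g/day (early-vs-late fruit+vegetable
  difference) and `z_slope = 0.03` per percentage point (the generative,
  age/gender-conditional slope of the z-score on percent-before). The
  generator converts these into per-component linear couplings using
  calibration constants — the realized mean/SD/early-late spread of
  percent-before and the realized component SDs — plus two scale factors
  that undo the small attenuation introduced by non-negativity floors.
  The distribution constants were frozen from a 150,000-adult fixed-point
  run of `calibrate_config()` (three iterations); the two scale factors
  were then sized against the replicate-study estimator itself (600
  regenerated 260-adult cohorts), since that estimator is what the
  generative targets are defined on. Rerun `calibrate_config()` after
  changing any timing or energy parameter;
* adult BMI is linear in age with slope 0.10 and residual SD 3.7,
  targeting the observed Spearman correlation with age of about 0.4;
  65% of anthropometry is flagged "measured", and about 2% is missing.

What the generator does **not** emulate: seasonality, region, physical
activity, the employment-to-late-eating association, under-reporting by
heavier subjects, and any measurement-error structure of real recalls
(within-person day-to-day nutrient variation is folded into the occasion
noise rather than modelled as usual-intake error). Passing tests on
synthetic data therefore demonstrate that the pipeline computes its
estimands correctly under a known data-generating process — not that the
survey's substantive findings generalize.

Realized timing marginals are close to, but not exactly at, the survey's
descriptive values (mean percent-before is about 57 versus the reported
61, SD 15 versus 18) because the generator fixes the *meal-level* means
and energies to their reported values and lets percent-before emerge. This
was left as is rather than distorting the stated meal parameters.

## Numerical and design choices

* Percent rounding in report tables is half-away-from-zero, the convention
  matching every checkable printed cell (18.65 to 19, 46.7 to 47).
* Largest-meal ties resolve to the earliest occasion; boundary
  conventions are: "before 16:00" strict, "at least 60%" inclusive,
  "after 20:00" strict, "within 1 h" inclusive.
* Degenerate inputs warn and skip rather than fail where a survey subset
  could plausibly produce them (an empty early or late group, a DQS
  category with fewer than two adults); they error where silence would
  corrupt results (zero energy, zero component SD, missing DQS inputs).
* Group percentages use the subjects with valid data for that variable as
  the denominator.
* Replicate studies (`recovery_report()`) derive replicate seeds as
  `seed + r`; all simulation sizes in the tests (up to 20,000 subjects for
  marginal checks, 200 replicates of 260 adults for recovery) were chosen
  so the whole suite runs in a few minutes on one CPU.

## Known limitations

* The sugar component scores total rather than added sugar (see above).
* `pct_energy_before` treats an occasion's entire energy as consumed at
  its start time; eating that straddles the cutoff is not split.
* The mixed-model contrasts use Wald z rather than Satterthwaite df;
  for the survey-scale n (hundreds of meals) the difference is far below
  reporting precision.
* The z-score depends on the cohort through its SDs, so z-values are not
  comparable across differently composed cohorts — by design, but worth
  restating.
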