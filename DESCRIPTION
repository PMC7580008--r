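Package: chronodiet
Title: Diet Quality and Meal-Timing Analysis for Two-Recall Dietary Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing nutrient-resolved 24-hour dietary recall
    surveys with two recall days per subject. Computes two-day averaged
    intake summaries with derived metrics (percent of energy from
    macronutrients via Atwater factors, fiber density, energy density),
    chrononutrition metrics (percent of energy consumed before a clock-time
    cutoff, largest-meal timing, early-eater and late-eating
    classifications, lunch-time consistency), a five-component Diet Quality
    Score against EU Science Hub recommendations together with its
    continuous z-score companion, and the accompanying statistical
    comparisons (t-tests, chi-square, Benjamini-Hochberg FDR, ANOVA with
    Tukey HSD, adjusted linear regression, and random-intercept mixed
    models of per-meal energy). A synthetic-cohort generator emulates the
    statistical structure of a national dietary survey so the full pipeline
    is reproducible without access to the survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    broom,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
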