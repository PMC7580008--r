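# End-to-end pipeline driver and report builder: nutrient summary with
# child-vs-adult tests, early/late and after-20:00 comparisons with BH-FDR,
# per-occasion summary, largest-meal and percent-before histogram data, and
# the DQS-category ANOVAs.

#' Round a count ratio to an integer percent
#'
#' `round(100 * numerator / denominator)` with half-away-from-zero rounding
#' (18.65 -> 19, 46.7 -> 47), the convention used in survey report tables.
#'
#' @param numerator,denominator Counts; `numerator <= denominator`,
#'   `denominator > 0`.
#' @return Integer percent.
#' @export
#' @examples
#' format_percent(34, 254) # 13
format_percent <- function(numerator, denominator) {
  if (any(denominator <= 0)) abort("denominator must be positive")
  if (any(numerator > denominator)) {
    abort("numerator must not exceed denominator")
  }
  if (any(numerator < 0)) abort("numerator must be non-negative")
  x <- 100 * numerator / denominator
  as.integer(floor(x + 0.5))
}

#' Convert grams per day to half-cup servings
#'
#' Using the convention of about 85 g of fruit or vegetables per half-cup
#' serving, 400 g/day is about 5 servings/day.
#'
#' @param grams_per_day Intake in g/day.
#' @param grams_per_serving Grams per serving, default 85.
#' @return Tibble: `grams_per_day`, `servings` (raw), `servings_rounded`.
#' @export
#' @examples
#' grams_to_servings(400) # 4.71 servings, about 5
grams_to_servings <- function(grams_per_day, grams_per_serving = 85) {
  if (grams_per_serving <= 0) abort("grams_per_serving must be positive")
  servings <- grams_per_day / grams_per_serving
  tibble::tibble(
    grams_per_day = grams_per_day,
    servings = servings,
    servings_rounded = as.integer(floor(servings + 0.5))
  )
}

#' Long table of main-meal energies
#'
#' One row per subject, recall day and main meal (breakfast/lunch/dinner)
#' with the meal's energy, the input format of [meal_energy_model()].
#'
#' @param recalls A valid recall table.
#' @param subjects Optional subjects table, used for `adults_only`.
#' @param adults_only Restrict to adult subjects.
#' @return Tibble: `subject_id`, `day`, `meal`, `kcal`.
#' @export
meal_energy_long <- function(recalls, subjects = NULL, adults_only = FALSE) {
  recalls <- validate_recalls(recalls)
  out <- recalls |>
    dplyr::filter(.data$label %in% meal_labels()) |>
    dplyr::transmute(
      subject_id = .data$subject_id, day = .data$day,
      meal = factor(.data$label, levels = meal_labels()),
      kcal = .data$energy
    )
  if (adults_only) {
    if (is.null(subjects)) abort("`subjects` is needed for adults_only")
    subjects <- validate_subjects(subjects)
    out <- dplyr::semi_join(
      out, dplyr::filter(subjects, !.data$is_child), by = "subject_id"
    )
  }
  out
}

# mean (SD) comparison of a set of variables between two subject groups,
# with BH-corrected two-sample t-test p-values
.group_comparison <- function(data, group_flag, vars, alpha = 0.05) {
  rows <- purrr::map_dfr(vars, function(v) {
    x <- data[[v]][group_flag]
    y <- data[[v]][!group_flag]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    # a constant variable (or a too-small group) yields NA, not a failure
    tt <- tryCatch(dq_t_test(x, y), error = function(e) NULL)
    tibble::tibble(
      variable = v,
      n_a = length(x), mean_a = mean(x), sd_a = sd(x),
      n_b = length(y), mean_b = mean(y), sd_b = sd(y),
      p_value = if (is.null(tt)) NA_real_ else tt$p_value
    )
  })
  rows$p_adjusted <- NA_real_
  rows$significant <- NA
  ok <- !is.na(rows$p_value)
  if (any(ok)) {
    fdr <- benjamini_hochberg(rows$p_value[ok], alpha = alpha)
    rows$p_adjusted[ok] <- fdr$p_adjusted
    rows$significant[ok] <- fdr$significant
  }
  rows
}

#' Run the full survey analysis pipeline
#'
#' Orchestrates the whole analysis on one dataset: per-subject intake
#' summaries and timing profiles, adult diet-quality scoring, and the
#' report tables — a nutrient summary with child-vs-adult t-tests and
#' BH-FDR; early-vs-late-eater and eats-after-20:00 comparisons of the
#' adult diet-quality variables; a per-occasion time/energy/consumer
#' summary; histogram bin counts of largest-meal time and percent-before by
#' DQS category; and DQS-category ANOVAs (with Tukey HSD) of percent-before
#' and log energy.
#'
#' @param recalls A valid recall table.
#' @param subjects A valid subjects table.
#' @param thresholds A [timing_thresholds()].
#' @param recommendations A [dq_recommendations()].
#' @param alpha FDR level for the comparison tables.
#' @return List of class `dq_report`; see Details.
#' @details The returned object carries `subject_intake`, `timing`,
#'   `adult_dqs` (per-subject scores and z-scores), and the tables
#'   `table_nutrients`, `table_early_late`, `table_after_cutoff`,
#'   `occasion_summary`, `largest_meal_hist`, `pct_before_hist`,
#'   `dqs_anova` plus the regression `z_regression`.
#' @export
run_pipeline <- function(recalls, subjects,
                         thresholds = timing_thresholds(),
                         recommendations = dq_recommendations(),
                         alpha = 0.05) {
  recalls <- validate_recalls(recalls)
  subjects <- validate_subjects(subjects)
  si <- subject_intake(recalls, subjects, cutoff = thresholds$cutoff)
  tp <- timing_profile(recalls, thresholds)
  si <- dplyr::left_join(
    si,
    dplyr::select(
      tp, "subject_id", "early_eater", "eats_after_cutoff",
      "largest_meal_time", "largest_meal_label", "lunch_day_gap",
      "lunch_within_1h"
    ),
    by = "subject_id"
  )
  adults <- dplyr::filter(si, !.data$is_child)
  if (nrow(adults) < 2) abort("pipeline stage diet_quality: need >= 2 adults")

  adult_dqs <- dqs_score(adults, recommendations)
  adult_dqs <- dqs_zscore(adult_dqs, recommendations)

  ## Table-2-style nutrient summary -----------------------------------------
  nutr_vars <- c(
    "energy", "carbohydrate_pct", "protein_pct", "fat_pct",
    "saturated_fat_pct", "fiber_density", "fruit", "vegetables", "fruit_veg",
    "sodium", "sugar_pct", "water", "protein_per_kg", "energy_density",
    "pct_energy_before_cutoff", "occasions_per_day"
  )
  table_nutrients <- if (sum(si$is_child) >= 2) {
    .group_comparison(si, si$is_child, nutr_vars, alpha) |>
      dplyr::rename(
        n_children = "n_a", mean_children = "mean_a", sd_children = "sd_a",
        n_adults = "n_b", mean_adults = "mean_b", sd_adults = "sd_b"
      )
  } else {
    warn("fewer than two children: skipping child-vs-adult comparison")
    NULL
  }

  ## Table-3-style early/late comparison ------------------------------------
  dq_vars <- c(
    "pct_energy_before_cutoff", "energy", "age", "bmi", "occasions_per_day",
    "energy_density", "fruit_veg", "fiber_density", "saturated_fat_pct",
    "sugar_pct", "sodium", "z_total"
  )
  compare_groups <- function(flag, stage) {
    if (length(unique(flag)) < 2) {
      warn(sprintf("degenerate grouping in %s: one group is empty", stage))
      return(NULL)
    }
    cont <- .group_comparison(
      adult_dqs, flag, intersect(dq_vars, names(adult_dqs)), alpha
    )
    # categorical rows: gender, DQS 4-5, employment (chi-square)
    cats <- list(
      female = adult_dqs$gender == "female",
      dqs_4_5 = adult_dqs$dqs_category == "4-5"
    )
    if ("employed_outside_home" %in% names(adult_dqs)) {
      cats$employed_outside_home <- adult_dqs$employed_outside_home
    }
    cat_rows <- purrr::map_dfr(names(cats), function(nm) {
      v <- cats[[nm]]
      ok <- !is.na(v)
      tab <- table(flag[ok], v[ok])
      p <- if (all(dim(tab) == c(2, 2)) && all(rowSums(tab) > 0) &&
               all(colSums(tab) > 0)) {
        dq_chi_square(tab)$p_value
      } else {
        NA_real_
      }
      tibble::tibble(
        variable = nm,
        n_a = sum(ok & flag), count_a = sum(v[ok & flag]),
        pct_a = format_percent(sum(v[ok & flag]), max(sum(ok & flag), 1)),
        n_b = sum(ok & !flag), count_b = sum(v[ok & !flag]),
        pct_b = format_percent(sum(v[ok & !flag]), max(sum(ok & !flag), 1)),
        p_value = p
      )
    })
    list(continuous = cont, categorical = cat_rows)
  }
  table_early_late <- compare_groups(adult_dqs$early_eater, "early_late")
  table_after_cutoff <- compare_groups(adult_dqs$eats_after_cutoff, "after_cutoff")

  ## Fig-1-style per-occasion summary ---------------------------------------
  occasion_summary <- recalls |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      n_consumers = dplyr::n_distinct(.data$subject_id),
      mean_time = mean(.data$time),
      mean_energy = mean(.data$energy),
      sd_energy = sd(.data$energy),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$label, occasion_labels()))

  ## Fig-2-style histogram data ---------------------------------------------
  hist_by_cat <- function(values, breaks) {
    purrr::map_dfr(levels(adult_dqs$dqs_category), function(cat) {
      v <- values[adult_dqs$dqs_category == cat]
      h <- hist(v, breaks = breaks, plot = FALSE, right = FALSE)
      tibble::tibble(
        dqs_category = cat, bin_left = h$breaks[-length(h$breaks)],
        bin_right = h$breaks[-1], count = h$counts
      )
    })
  }
  largest_meal_hist <- hist_by_cat(
    adult_dqs$largest_meal_time, breaks = seq(0, 1440, by = 60)
  )
  pct_before_hist <- hist_by_cat(
    adult_dqs$pct_energy_before_cutoff, breaks = seq(0, 100, by = 10)
  )

  ## DQS-category ANOVAs -----------------------------------------------------
  cat_n <- table(adult_dqs$dqs_category)
  usable <- adult_dqs$dqs_category %in% names(cat_n)[cat_n >= 2]
  dqs_anova <- if (sum(cat_n >= 2) >= 2) {
    if (!all(usable)) {
      warn("dropping DQS categories with fewer than two adults from the ANOVA")
    }
    list(
      pct_before = anova_tukey(
        adult_dqs$pct_energy_before_cutoff[usable],
        adult_dqs$dqs_category[usable]
      ),
      log_energy = anova_tukey(
        adult_dqs$energy[usable], adult_dqs$dqs_category[usable],
        log_transform = TRUE
      )
    )
  } else {
    warn("degenerate grouping in dqs_anova: fewer than two populated categories")
    NULL
  }

  ## z-score trend regression ------------------------------------------------
  adult_dqs$female <- adult_dqs$gender == "female"
  safe_ols <- function(formula) {
    tryCatch(dq_ols(adult_dqs, formula), error = function(e) {
      warn(sprintf("stage z_regression skipped: %s", conditionMessage(e)))
      NULL
    })
  }
  z_regression <- list(
    unadjusted = safe_ols(z_total ~ pct_energy_before_cutoff),
    adjusted = safe_ols(z_total ~ pct_energy_before_cutoff + age + female)
  )

  out <- list(
    subject_intake = si,
    timing = tp,
    adult_dqs = adult_dqs,
    table_nutrients = table_nutrients,
    table_early_late = table_early_late,
    table_after_cutoff = table_after_cutoff,
    occasion_summary = occasion_summary,
    largest_meal_hist = largest_meal_hist,
    pct_before_hist = pct_before_hist,
    dqs_anova = dqs_anova,
    z_regression = z_regression,
    thresholds = thresholds,
    recommendations = recommendations,
    alpha = alpha
  )
  class(out) <- "dq_report"
  out
}

#' @export
print.dq_report <- function(x, ...) {
  cat("Diet-quality and meal-timing survey report\n")
  cat("  subjects:", nrow(x$subject_intake),
      "(", sum(!x$subject_intake$is_child), "adults )\n")
  ad <- x$adult_dqs
  cat("  adult DQS mean:", round(mean(ad$dqs), 2),
      "| z-score mean:", round(mean(ad$z_total), 2), "\n")
  cat("  early eaters:", sum(ad$early_eater), "of", nrow(ad), "\n")
  invisible(x)
}

#' @export
glance.dq_report <- function(x, ...) {
  ad <- x$adult_dqs
  tibble::tibble(
    n_subjects = nrow(x$subject_intake),
    n_adults = nrow(ad),
    mean_energy = mean(x$subject_intake$energy),
    mean_pct_before = mean(ad$pct_energy_before_cutoff),
    mean_dqs = mean(ad$dqs),
    mean_z_total = mean(ad$z_total),
    n_early = sum(ad$early_eater),
    n_after_cutoff = sum(ad$eats_after_cutoff)
  )
}

#' @export
tidy.dq_report <- function(x, ...) {
  bind_part <- function(tbl, part) {
    if (is.null(tbl)) return(NULL)
    dplyr::mutate(tbl$continuous, table = part, .before = 1)
  }
  dplyr::bind_rows(
    if (!is.null(x$table_nutrients)) {
      dplyr::mutate(
        dplyr::rename(
          x$table_nutrients,
          n_a = "n_children", mean_a = "mean_children", sd_a = "sd_children",
          n_b = "n_adults", mean_b = "mean_adults", sd_b = "sd_adults"
        ),
        table = "nutrients", .before = 1
      )
    },
    bind_part(x$table_early_late, "early_late"),
    bind_part(x$table_after_cutoff, "after_cutoff")
  )
}
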