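# Chrononutrition metrics: percent of energy before a clock cutoff,
# largest-meal identification, eater classifications, lunch consistency.
# Only occasion START times exist in recall data, so "before 16:00" means
# the occasion starts strictly before the cutoff.

#' Meal-timing thresholds
#'
#' @param cutoff Clock cutoff in minutes since midnight for "early" energy
#'   (default 960 = 16:00).
#' @param early_pct Percent of daily energy before `cutoff` at or above which
#'   a subject is an early eater (default 60; the comparison is inclusive,
#'   "at least 60%").
#' @param late_meal Clock time in minutes; an occasion starting strictly
#'   after it counts as eating late (default 1200 = 20:00).
#' @return A list of class `timing_thresholds`.
#' @export
timing_thresholds <- function(cutoff = 960, early_pct = 60, late_meal = 1200) {
  stopifnot(cutoff > 0, cutoff < 1440, early_pct > 0, early_pct <= 100,
            late_meal > 0, late_meal < 1440)
  structure(
    list(cutoff = cutoff, early_pct = early_pct, late_meal = late_meal),
    class = "timing_thresholds"
  )
}

#' Percent of energy consumed before a clock cutoff
#'
#' By default pools energy over both recall days (ratio of sums), which
#' equals average kcal before the cutoff divided by average daily energy;
#' `method = "per_day"` instead averages the two daily percentages.
#'
#' @param recalls A valid recall table.
#' @param cutoff Cutoff in minutes since midnight (default 960 = 16:00);
#'   occasions count when they start strictly before it.
#' @param method `"pooled"` (default) or `"per_day"`.
#' @return Tibble: `subject_id`, `pct_energy_before_cutoff`.
#' @export
#' @examples
#' # 600 kcal at 9:00 + 400 kcal at 20:00 on both days -> 60%
pct_energy_before <- function(recalls, cutoff = 960,
                              method = c("pooled", "per_day")) {
  method <- match.arg(method)
  recalls <- validate_recalls(recalls)
  per_day <- recalls |>
    dplyr::group_by(.data$subject_id, .data$day) |>
    dplyr::summarise(
      before = sum(.data$energy[.data$time < cutoff]),
      total = sum(.data$energy),
      .groups = "drop"
    )
  if (any(per_day$total <= 0)) {
    abort("percent of energy before cutoff is undefined for a day with zero energy")
  }
  if (method == "pooled") {
    per_day |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::summarise(
        pct_energy_before_cutoff = 100 * sum(.data$before) / sum(.data$total),
        .groups = "drop"
      )
  } else {
    per_day |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::summarise(
        pct_energy_before_cutoff = mean(100 * .data$before / .data$total),
        .groups = "drop"
      )
  }
}

#' Classify early eaters
#'
#' An early eater consumes at least `early_pct` percent of daily energy
#' before the cutoff (inclusive comparison).
#'
#' @param pct Numeric vector of percent-of-energy-before-cutoff values.
#' @param early_pct Threshold percent, default 60.
#' @return Logical vector.
#' @export
classify_early_eater <- function(pct, early_pct = 60) {
  pct >= early_pct
}

#' Classify eating after a late clock time
#'
#' Flags subjects with any occasion starting strictly after `late_meal` on
#' either recall day (the strictest observable version of habitual late
#' eating on two days).
#'
#' @param recalls A valid recall table.
#' @param late_meal Clock time in minutes, default 1200 (20:00).
#' @return Tibble: `subject_id`, `eats_after_cutoff`.
#' @export
classify_after_time <- function(recalls, late_meal = 1200) {
  recalls <- validate_recalls(recalls)
  recalls |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      eats_after_cutoff = any(.data$time > late_meal),
      .groups = "drop"
    )
}

#' Largest meal of the day
#'
#' Per recall day, the eating occasion (meal or snack) with the highest
#' energy content; ties are broken by the earliest start time. The reported
#' `largest_meal_time` is the arithmetic mean of the per-day largest-meal
#' start times, even when the winning occasion differs between days.
#'
#' @param recalls A valid recall table.
#' @return Tibble: `subject_id`, per-day winners in `largest_meal_by_day`
#'   (list of per-day tibbles), `largest_meal_time` (mean minutes since
#'   midnight), and `largest_meal_label` (day-1 winner, the modal summary
#'   used in report tables).
#' @export
largest_meal <- function(recalls) {
  recalls <- validate_recalls(recalls)
  per_day <- recalls |>
    dplyr::group_by(.data$subject_id, .data$day) |>
    dplyr::arrange(dplyr::desc(.data$energy), .data$time, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select("subject_id", "day", "label", "time", "energy")
  per_day |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      largest_meal_by_day = list(dplyr::pick("day", "label", "time", "energy")),
      largest_meal_time = mean(.data$time),
      largest_meal_label = .data$label[1],
      .groups = "drop"
    )
}

#' Mean occasion start times
#'
#' Per subject and occasion label, the mean start time over the recall days
#' on which the label occurs (one or two days).
#'
#' @param recalls A valid recall table.
#' @return Tibble: `subject_id`, `label`, `mean_time` (minutes),
#'   `days_present`.
#' @export
mean_occasion_times <- function(recalls) {
  recalls <- validate_recalls(recalls)
  recalls |>
    dplyr::group_by(.data$subject_id, .data$label) |>
    dplyr::summarise(
      mean_time = mean(.data$time),
      days_present = dplyr::n(),
      .groups = "drop"
    )
}

#' Between-day lunch-time consistency
#'
#' Absolute difference in lunch start time between the two recall days, and
#' whether it is within one hour (inclusive). Subjects missing lunch on
#' either day get `NA` rather than an error.
#'
#' @param recalls A valid recall table.
#' @return Tibble: `subject_id`, `lunch_day_gap` (minutes), `lunch_within_1h`.
#' @export
lunch_consistency <- function(recalls) {
  recalls <- validate_recalls(recalls)
  recalls |>
    dplyr::filter(.data$label == "lunch") |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      lunch_day_gap = if (dplyr::n() == 2) abs(diff(.data$time)) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::right_join(
      dplyr::distinct(recalls, .data$subject_id),
      by = "subject_id"
    ) |>
    dplyr::mutate(lunch_within_1h = .data$lunch_day_gap <= 60)
}

#' Per-subject meal-timing profile
#'
#' Combines the timing metrics into one row per subject: percent of energy
#' before the cutoff, the early-eater and eats-after-20:00 flags,
#' largest-meal timing, lunch-time consistency, and occasions per day.
#'
#' @param recalls A valid recall table.
#' @param thresholds A [timing_thresholds()] object.
#' @param method Percent-before aggregation, `"pooled"` (default) or
#'   `"per_day"`; see [pct_energy_before()].
#' @return Tibble with one row per subject.
#' @export
timing_profile <- function(recalls, thresholds = timing_thresholds(),
                           method = c("pooled", "per_day")) {
  method <- match.arg(method)
  stopifnot(inherits(thresholds, "timing_thresholds"))
  recalls <- validate_recalls(recalls)
  pct <- pct_energy_before(recalls, cutoff = thresholds$cutoff, method = method)
  late <- classify_after_time(recalls, late_meal = thresholds$late_meal)
  lm_tbl <- largest_meal(recalls)
  lunch <- lunch_consistency(recalls)
  occ <- recalls |>
    dplyr::count(.data$subject_id, .data$day) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(occasions_per_day = mean(.data$n), .groups = "drop")
  pct |>
    dplyr::mutate(
      early_eater = classify_early_eater(
        .data$pct_energy_before_cutoff, thresholds$early_pct
      )
    ) |>
    dplyr::left_join(late, by = "subject_id") |>
    dplyr::left_join(lm_tbl, by = "subject_id") |>
    dplyr::left_join(lunch, by = "subject_id") |>
    dplyr::left_join(occ, by = "subject_id")
}
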