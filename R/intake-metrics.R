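# Per-day totals and two-day-averaged subject intake summaries.

#' Atwater energy-conversion factors
#'
#' Conventional factors (kcal per gram) used to express macronutrient intakes
#' as a percentage of energy: carbohydrate 4, protein 4, fat 9, alcohol 7.
#' Saturated fat uses the fat factor and sugar the carbohydrate factor.
#'
#' @return Named numeric vector of kcal/g factors.
#' @export
atwater_factors <- function() {
  c(carbohydrate = 4, protein = 4, fat = 9, alcohol = 7)
}

#' Percent of energy from a nutrient
#'
#' `100 * grams * kcal_per_gram / energy`. The energy denominator is the
#' reported (database-derived) intake, not a value recomputed from
#' macronutrients, so percentage fields need not sum to 100 on real data.
#'
#' @param grams Nutrient intake, g/day.
#' @param kcal_per_gram Atwater factor for the nutrient.
#' @param energy Energy intake, kcal/day; must be positive.
#' @return Percent of energy.
#' @export
#' @examples
#' percent_energy_from(20, 9, 500) # 36
percent_energy_from <- function(grams, kcal_per_gram, energy) {
  if (any(energy <= 0)) {
    abort("percent of energy is undefined for non-positive energy intake")
  }
  100 * grams * kcal_per_gram / energy
}

#' Per-day intake totals
#'
#' Sums each quantity over the eating occasions of every recall day and
#' counts occasions; also accumulates energy from occasions starting strictly
#' before `cutoff` (used downstream by the timing metrics).
#'
#' @param recalls A valid recall table.
#' @param cutoff Clock cutoff in minutes since midnight (default 960, i.e.
#'   16:00) for the energy-before-cutoff accumulator.
#' @return Tibble with one row per (subject, day): quantity totals,
#'   `occasion_count` and `energy_before_cutoff`.
#' @export
daily_intake <- function(recalls, cutoff = 960) {
  recalls <- validate_recalls(recalls)
  recalls |>
    dplyr::group_by(.data$subject_id, .data$day) |>
    dplyr::summarise(
      energy_before_cutoff = sum(.data$energy[.data$time < cutoff]),
      occasion_count = dplyr::n(),
      dplyr::across(dplyr::all_of(.occasion_quantities), sum),
      .groups = "drop"
    )
}

#' Two-day averaged subject intake summary
#'
#' Averages the two recall days of every subject and derives the standard
#' survey metrics from the averaged intakes (ratio of means, not mean of
#' ratios): percent of energy from carbohydrate, protein, fat, saturated fat,
#' sugar and alcohol via Atwater factors; fiber density (g/1000 kcal);
#' combined fruit-and-vegetable intake; energy density (kcal per gram of
#' food, the food-mass denominator excluding drinking water and beverages);
#' percent of energy consumed before the cutoff; and, when subject weights
#' are supplied, protein per kg body weight (left `NA`, not an error, where
#' weight is missing).
#'
#' @param recalls A valid recall table with two days per subject.
#' @param subjects Optional subjects table; when present, `protein_per_kg`
#'   and demographic columns are joined in.
#' @param cutoff Clock cutoff in minutes (default 960 = 16:00).
#' @return Tibble with one row per subject.
#' @export
subject_intake <- function(recalls, subjects = NULL, cutoff = 960) {
  daily <- daily_intake(recalls, cutoff = cutoff)
  n_days <- daily |> dplyr::count(.data$subject_id)
  if (any(n_days$n != 2)) {
    warn(sprintf(
      "%d subject(s) do not have exactly two recall days; averaging available days",
      sum(n_days$n != 2)
    ))
  }
  fac <- atwater_factors()
  out <- daily |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      dplyr::across(
        dplyr::all_of(c(
          .occasion_quantities, "energy_before_cutoff", "occasion_count"
        )),
        mean
      ),
      .groups = "drop"
    ) |>
    dplyr::rename(occasions_per_day = "occasion_count") |>
    dplyr::mutate(
      carbohydrate_pct = percent_energy_from(.data$carbohydrate, fac[["carbohydrate"]], .data$energy),
      protein_pct = percent_energy_from(.data$protein, fac[["protein"]], .data$energy),
      fat_pct = percent_energy_from(.data$fat, fac[["fat"]], .data$energy),
      saturated_fat_pct = percent_energy_from(.data$saturated_fat, fac[["fat"]], .data$energy),
      sugar_pct = percent_energy_from(.data$sugar, fac[["carbohydrate"]], .data$energy),
      alcohol_pct = percent_energy_from(.data$alcohol, fac[["alcohol"]], .data$energy),
      fiber_density = 1000 * .data$fiber / .data$energy,
      fruit_veg = .data$fruit + .data$vegetables,
      energy_density = .data$energy / .data$food_mass,
      pct_energy_before_cutoff = 100 * .data$energy_before_cutoff / .data$energy
    )
  if (!is.null(subjects)) {
    subjects <- validate_subjects(subjects)
    out <- dplyr::left_join(out, subjects, by = "subject_id")
    if (!("weight" %in% names(out))) out$weight <- NA_real_
    out$protein_per_kg <- ifelse(
      !is.na(out$weight) & out$weight > 0, out$protein / out$weight, NA_real_
    )
  }
  out
}
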