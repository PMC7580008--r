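# Five-component Diet Quality Score (DQS) against EU Science Hub
# recommendations, and its continuous z-score companion.

#' Dietary recommendations used by the Diet Quality Score
#'
#' One DQS point is awarded per recommendation met: fruit and vegetables at
#' least 400 g/day, fiber at least 14 g/1000 kcal, sugar below 10% of
#' energy, saturated fat below 10% of energy, and sodium below 2.3 g/day.
#' Meeting a minimum is inclusive (`>=`); the three limits are strict (`<`)
#' by default but the operators are configurable.
#'
#' @param fv_min Fruit+vegetables minimum, g/day.
#' @param fiber_min Fiber-density minimum, g/1000 kcal.
#' @param sugar_max Sugar limit, percent of energy.
#' @param satfat_max Saturated-fat limit, percent of energy.
#' @param sodium_max Sodium limit, g/day.
#' @param strict_limits If `TRUE` (default) the sugar, saturated-fat and
#'   sodium comparisons are strict `<`; if `FALSE`, `<=`.
#' @return A list of class `dq_recommendations`.
#' @export
dq_recommendations <- function(fv_min = 400, fiber_min = 14, sugar_max = 10,
                               satfat_max = 10, sodium_max = 2.3,
                               strict_limits = TRUE) {
  vals <- c(fv_min, fiber_min, sugar_max, satfat_max, sodium_max)
  if (any(vals <= 0)) abort("all recommendation thresholds must be positive")
  structure(
    list(
      fv_min = fv_min, fiber_min = fiber_min, sugar_max = sugar_max,
      satfat_max = satfat_max, sodium_max = sodium_max,
      strict_limits = strict_limits
    ),
    class = "dq_recommendations"
  )
}

# the five scored components, their SubjectIntake columns, and z-score signs
# (+1: exceeding the recommendation is healthy; -1: exceeding the limit is not)
dqs_components <- function() {
  tibble::tibble(
    component = c("fv", "fiber", "sugar", "satfat", "sodium"),
    column = c(
      "fruit_veg", "fiber_density", "sugar_pct", "saturated_fat_pct", "sodium"
    ),
    sign = c(1, 1, -1, -1, -1)
  )
}

.dqs_reference <- function(rec) {
  c(fv = rec$fv_min, fiber = rec$fiber_min, sugar = rec$sugar_max,
    satfat = rec$satfat_max, sodium = rec$sodium_max)
}

.check_dqs_columns <- function(intake) {
  comps <- dqs_components()
  for (i in seq_len(nrow(comps))) {
    col <- comps$column[i]
    if (!col %in% names(intake)) {
      abort(sprintf(
        "DQS component `%s` requires column `%s`, which is missing",
        comps$component[i], col
      ))
    }
    if (any(is.na(intake[[col]]))) {
      abort(sprintf(
        "DQS component `%s` has missing values in `%s`; the score is undefined, not partial",
        comps$component[i], col
      ))
    }
  }
  invisible(intake)
}

#' Score the Diet Quality Score (0-5)
#'
#' Adds the five per-component verdicts, the DQS (count of recommendations
#' met) and its ordinal category to a subject-intake table.
#'
#' @param intake Subject-intake tibble (see [subject_intake()]) with columns
#'   `fruit_veg`, `fiber_density`, `sugar_pct`, `saturated_fat_pct`,
#'   `sodium`.
#' @param rec A [dq_recommendations()] object.
#' @return `intake` with logical columns `met_fv`, `met_fiber`, `met_sugar`,
#'   `met_satfat`, `met_sodium`, integer `dqs` and factor `dqs_category`.
#' @export
#' @examples
#' # adult population means: only the fruit-and-vegetable recommendation met
#' x <- tibble::tibble(
#'   subject_id = "mean_adult", fruit_veg = 473, fiber_density = 10.9,
#'   sugar_pct = 13.2, saturated_fat_pct = 13, sodium = 3.99
#' )
#' dqs_score(x)$dqs # 1
dqs_score <- function(intake, rec = dq_recommendations()) {
  stopifnot(inherits(rec, "dq_recommendations"))
  intake <- tibble::as_tibble(intake)
  .check_dqs_columns(intake)
  below <- if (rec$strict_limits) `<` else `<=`
  out <- intake |>
    dplyr::mutate(
      met_fv = .data$fruit_veg >= rec$fv_min,
      met_fiber = .data$fiber_density >= rec$fiber_min,
      met_sugar = below(.data$sugar_pct, rec$sugar_max),
      met_satfat = below(.data$saturated_fat_pct, rec$satfat_max),
      met_sodium = below(.data$sodium, rec$sodium_max),
      dqs = as.integer(.data$met_fv) + .data$met_fiber + .data$met_sugar +
        .data$met_satfat + .data$met_sodium,
      dqs_category = dqs_category(.data$dqs)
    )
  out
}

#' Ordinal DQS category
#'
#' Bins DQS values into the ordinal categories 0-1, 2-3 and 4-5.
#'
#' @param dqs Integer vector of DQS values in 0-5.
#' @return Factor with levels `0-1`, `2-3`, `4-5`.
#' @export
dqs_category <- function(dqs) {
  if (any(is.na(dqs)) || any(dqs < 0 | dqs > 5) || any(dqs != floor(dqs))) {
    abort("dqs must be an integer in 0-5")
  }
  cut(dqs, breaks = c(-0.5, 1.5, 3.5, 5.5), labels = c("0-1", "2-3", "4-5"))
}

#' Diet Quality z-score
#'
#' The continuous companion of the DQS: for each component, the signed
#' standardized deviation of intake from its recommended value,
#' `z = sign * (x - r) / SD`, where the SD is the sample standard deviation
#' (n-1 denominator) of that intake over the supplied cohort. The sign is +1
#' for fruit/vegetables and fiber (exceeding the recommendation is good) and
#' -1 for sugar, saturated fat and sodium (exceeding the limit is bad). The
#' z-score total is the sum of the five components. The cohort over which
#' SDs are taken is exactly the table passed in — typically the adult
#' analysis cohort — never global state.
#'
#' @param intake Subject-intake tibble with at least two subjects.
#' @param rec A [dq_recommendations()] object.
#' @return `intake` with columns `z_fv`, `z_fiber`, `z_sugar`, `z_satfat`,
#'   `z_sodium` and `z_total`. The per-component SDs are attached as the
#'   `"component_sd"` attribute.
#' @export
dqs_zscore <- function(intake, rec = dq_recommendations()) {
  stopifnot(inherits(rec, "dq_recommendations"))
  intake <- tibble::as_tibble(intake)
  .check_dqs_columns(intake)
  if (nrow(intake) < 2) {
    abort("z-scores need at least two subjects to estimate component SDs")
  }
  comps <- dqs_components()
  ref <- .dqs_reference(rec)
  sds <- setNames(numeric(nrow(comps)), comps$component)
  for (i in seq_len(nrow(comps))) {
    x <- intake[[comps$column[i]]]
    s <- sd(x)
    if (s == 0) {
      abort(sprintf(
        "degenerate cohort: component `%s` has zero standard deviation",
        comps$component[i]
      ))
    }
    sds[comps$component[i]] <- s
    intake[[paste0("z_", comps$component[i])]] <-
      comps$sign[i] * (x - ref[[comps$component[i]]]) / s
  }
  intake$z_total <- intake$z_fv + intake$z_fiber + intake$z_sugar +
    intake$z_satfat + intake$z_sodium
  attr(intake, "component_sd") <- sds
  intake
}
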