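# Data model for two-day 24-h recall surveys: one row per (subject, day,
# eating occasion), plus a per-subject demographics table.

#' Eating-occasion slot labels
#'
#' The eight labelled eating occasions a recall day may contain, in canonical
#' clock order. Two afternoon-snack slots are distinct labels because some
#' subjects report two afternoon snacks; a day holds at most one occasion per
#' label.
#'
#' @return Character vector of the eight occasion labels.
#' @export
#' @examples
#' occasion_labels()
occasion_labels <- function() {
  c(
    "pre_breakfast", "breakfast", "morning_snack", "lunch",
    "afternoon_snack_1", "afternoon_snack_2", "dinner", "after_dinner_snack"
  )
}

#' Main-meal labels
#'
#' @return Character vector: breakfast, lunch, dinner.
#' @export
meal_labels <- function() c("breakfast", "lunch", "dinner")

# nutrient/quantity columns of a recall table, all non-negative
.occasion_quantities <- c(
  "energy", "carbohydrate", "protein", "fat", "saturated_fat", "sugar",
  "fiber", "sodium", "fruit", "vegetables", "water", "food_mass", "alcohol"
)

#' Required columns of a recall table
#'
#' @return Character vector naming the columns every recall table must carry:
#'   `subject_id`, `day` (1 or 2), `label` (see [occasion_labels()]), `time`
#'   (minutes since midnight, or `"HH:MM"` on file), and the thirteen
#'   quantity columns (energy in kcal; carbohydrate, protein, fat,
#'   saturated_fat, sugar, fiber, sodium, fruit, vegetables, food_mass and
#'   alcohol in grams; water in millilitres).
#' @export
recall_columns <- function() {
  c("subject_id", "day", "label", "time", .occasion_quantities)
}

#' Parse clock times to minutes since midnight
#'
#' Accepts `"HH:MM"` strings or already-numeric minutes; values must fall in
#' `[0, 1439]` (occasions are assumed to lie within one calendar day).
#'
#' @param x Character `"HH:MM"` or numeric minutes.
#' @return Integer minutes since midnight.
#' @export
#' @examples
#' parse_clock_time("15:15") # 915
parse_clock_time <- function(x) {
  if (inherits(x, "difftime")) {
    # readr parses "HH:MM" columns as hms (seconds since midnight)
    mins <- as.numeric(x, units = "secs") / 60
  } else if (is.numeric(x)) {
    mins <- x
  } else {
    x <- as.character(x)
    hm <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))
    bad <- lengths(hm) != 3 & !is.na(x)
    if (any(bad)) {
      abort(sprintf(
        "invalid clock time(s): %s",
        paste(unique(x[bad]), collapse = ", ")
      ))
    }
    mins <- vapply(hm, function(m) {
      if (length(m) != 3) return(NA_real_)
      as.numeric(m[2]) * 60 + as.numeric(m[3])
    }, numeric(1))
  }
  out_of_range <- !is.na(mins) & (mins < 0 | mins > 1439)
  if (any(out_of_range)) {
    abort(sprintf(
      "clock time out of range [0, 1439]: %s",
      paste(unique(mins[out_of_range]), collapse = ", ")
    ))
  }
  as.integer(round(mins))
}

#' Format minutes since midnight as "HH:MM"
#'
#' @param minutes Numeric minutes since midnight.
#' @return Character `"HH:MM"`.
#' @export
format_clock_time <- function(minutes) {
  sprintf("%02d:%02d", floor(minutes / 60), round(minutes) %% 60)
}

#' Validate a recall table
#'
#' Checks the structural invariants of a recall table: required columns
#' present, days in \{1, 2\}, occasion labels drawn from [occasion_labels()]
#' and unique within a (subject, day), start times in `[0, 1439]`, all
#' quantities non-negative, and one to eight occasions per day.
#'
#' @param recalls A recall data frame (see [recall_columns()]).
#' @return The validated table, invisibly, with rows ordered by subject, day
#'   and start time.
#' @export
validate_recalls <- function(recalls) {
  recalls <- tibble::as_tibble(recalls)
  missing_cols <- setdiff(recall_columns(), names(recalls))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "recall table is missing required column(s): %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(recalls) == 0) abort("recall table has no rows")
  if (!all(recalls$day %in% c(1L, 2L))) {
    abort("`day` must be 1 or 2")
  }
  bad_label <- !recalls$label %in% occasion_labels()
  if (any(bad_label)) {
    abort(sprintf(
      "unknown occasion label(s): %s",
      paste(unique(recalls$label[bad_label]), collapse = ", ")
    ))
  }
  if (any(is.na(recalls$time)) || any(recalls$time < 0 | recalls$time > 1439)) {
    abort("occasion `time` must be in [0, 1439] minutes since midnight")
  }
  for (col in .occasion_quantities) {
    v <- recalls[[col]]
    if (any(is.na(v))) {
      abort(sprintf("column `%s` contains missing values", col))
    }
    if (any(v < 0)) {
      abort(sprintf(
        "negative quantity in column `%s` (row %d)", col, which(v < 0)[1]
      ))
    }
  }
  dup <- recalls |>
    dplyr::count(.data$subject_id, .data$day, .data$label) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf(
      "duplicate occasion label within a recall day: subject %s, day %d, label %s",
      dup$subject_id[1], dup$day[1], dup$label[1]
    ))
  }
  n_occ <- recalls |> dplyr::count(.data$subject_id, .data$day)
  if (any(n_occ$n > 8)) {
    abort("a recall day may contain at most eight eating occasions")
  }
  recalls <- dplyr::arrange(recalls, .data$subject_id, .data$day, .data$time)
  invisible(recalls)
}

#' Read a recall table from delimited text
#'
#' Reads a CSV with one row per (subject, day, occasion). Times may be given
#' as `"HH:MM"` or as integer minutes since midnight; they are stored as
#' minutes. The table is validated on read (see [validate_recalls()]).
#'
#' @param path Path to a CSV file.
#' @param schema Optional named character vector mapping required column
#'   names (see [recall_columns()]) to the names used in the file, e.g.
#'   `c(subject_id = "id", time = "start")`.
#' @return A validated tibble of eating occasions.
#' @export
read_recall_table <- function(path, schema = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(schema)) {
    for (std in names(schema)) {
      if (!schema[[std]] %in% names(raw)) {
        abort(sprintf(
          "schema maps `%s` to `%s`, which is not a column of %s",
          std, schema[[std]], path
        ))
      }
      names(raw)[names(raw) == schema[[std]]] <- std
    }
  }
  missing_cols <- setdiff(recall_columns(), names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      path, paste(missing_cols, collapse = ", ")
    ))
  }
  raw$time <- parse_clock_time(raw$time)
  raw$day <- as.integer(raw$day)
  raw$subject_id <- as.character(raw$subject_id)
  out <- validate_recalls(raw[recall_columns()])
  tibble::as_tibble(out)
}

#' Write a recall table to CSV
#'
#' Inverse of [read_recall_table()]: writing then reading a valid table
#' reproduces it field for field (times are written as integer minutes).
#'
#' @param recalls A valid recall table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recall_table <- function(recalls, path) {
  recalls <- validate_recalls(recalls)
  readr::write_csv(recalls[recall_columns()], path, progress = FALSE)
  invisible(path)
}

#' Assign survey age categories
#'
#' Maps ages to the survey's five age categories: children 10-17, adult
#' tertiles (defaults 18-29, 30-47, 48-64), and 65-74 (retirement age). The
#' category boundaries are half-open intervals on integer year labels, so
#' age 17.9 is still a child and age 18 falls in the first adult tertile.
#'
#' @param age Numeric vector of ages in years, each in `[10, 74]`.
#' @param tertile_breaks Lower bounds of the three adult tertiles and the
#'   retirement category, defaults `c(18, 30, 48, 65)`.
#' @return Factor with levels `10-17`, `18-29`, `30-47`, `48-64`, `65-74`
#'   (labels follow `tertile_breaks`).
#' @export
#' @examples
#' assign_age_category(c(14, 17.9, 18, 65))
assign_age_category <- function(age, tertile_breaks = c(18, 30, 48, 65)) {
  if (any(is.na(age)) || any(age < 10 | age >= 75)) {
    abort("age must be in [10, 74]; ages outside the surveyed range are not supported")
  }
  stopifnot(length(tertile_breaks) == 4, !is.unsorted(tertile_breaks))
  lower <- c(10, tertile_breaks)
  upper <- c(tertile_breaks - 1, 74)
  labels <- paste0(lower, "-", upper)
  cut(age, breaks = c(lower, 75), labels = labels, right = FALSE)
}

#' Validate a subjects table
#'
#' @param subjects Data frame with at least `subject_id`, `age`, `gender`
#'   (`"female"`/`"male"`) and `is_child`; `weight` (kg) and `height` (cm)
#'   may be present with missing values (BMI-dependent outputs then exclude
#'   those subjects rather than failing).
#' @return The validated tibble, invisibly, with an `age_category` column
#'   added when absent.
#' @export
validate_subjects <- function(subjects) {
  subjects <- tibble::as_tibble(subjects)
  needed <- c("subject_id", "age", "gender", "is_child")
  missing_cols <- setdiff(needed, names(subjects))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "subjects table is missing required column(s): %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (anyDuplicated(subjects$subject_id)) abort("duplicate subject_id")
  if (!all(subjects$gender %in% c("female", "male"))) {
    abort("gender must be \"female\" or \"male\"")
  }
  if (!("age_category" %in% names(subjects))) {
    subjects$age_category <- assign_age_category(subjects$age)
  }
  invisible(subjects)
}
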