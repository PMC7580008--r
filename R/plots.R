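# ggplot2 views of the report: per-occasion energy profile and the
# timing histograms stratified by DQS category.

#' Mean energy by eating occasion
#'
#' Bar chart of mean occasion energy (with SD error bars) across the eight
#' occasion slots, labelled with mean start times and consumer counts.
#'
#' @param report A `dq_report` from [run_pipeline()].
#' @return A ggplot object.
#' @export
plot_occasion_energy <- function(report) {
  stopifnot(inherits(report, "dq_report"))
  d <- report$occasion_summary
  d$label <- factor(d$label, levels = occasion_labels())
  ggplot2::ggplot(d, ggplot2::aes(x = .data$label, y = .data$mean_energy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = pmax(.data$mean_energy - .data$sd_energy, 0),
        ymax = .data$mean_energy + .data$sd_energy
      ),
      width = 0.3
    ) +
    ggplot2::geom_text(
      ggplot2::aes(label = format_clock_time(.data$mean_time), y = 0),
      vjust = 1.5, size = 3
    ) +
    ggplot2::labs(
      x = NULL, y = "Mean energy (kcal)",
      title = "Energy by eating occasion",
      subtitle = "labels show mean start time"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Largest-meal timing by DQS category
#'
#' Histogram (hourly bins) of the time the largest meal of the day was
#' consumed, one panel per DQS category.
#'
#' @param report A `dq_report`.
#' @return A ggplot object.
#' @export
plot_largest_meal_hist <- function(report) {
  stopifnot(inherits(report, "dq_report"))
  d <- report$largest_meal_hist
  ggplot2::ggplot(
    d,
    ggplot2::aes(x = (.data$bin_left + .data$bin_right) / 2 / 60, y = .data$count)
  ) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::facet_wrap(~dqs_category, ncol = 1) +
    ggplot2::labs(
      x = "Largest-meal time (h)", y = "Adults",
      title = "Timing of the largest meal by Diet Quality Score"
    ) +
    ggplot2::theme_minimal()
}

#' Percent of energy before the cutoff by DQS category
#'
#' @param report A `dq_report`.
#' @return A ggplot object.
#' @export
plot_pct_before_hist <- function(report) {
  stopifnot(inherits(report, "dq_report"))
  d <- report$pct_before_hist
  ggplot2::ggplot(
    d,
    ggplot2::aes(x = (.data$bin_left + .data$bin_right) / 2, y = .data$count)
  ) +
    ggplot2::geom_col(fill = "seagreen") +
    ggplot2::facet_wrap(~dqs_category, ncol = 1) +
    ggplot2::labs(
      x = "% of energy before cutoff", y = "Adults",
      title = "Early energy intake by Diet Quality Score"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dq_report <- function(object, which = c("occasions", "largest_meal", "pct_before"), ...) {
  which <- match.arg(which)
  switch(
    which,
    occasions = plot_occasion_energy(object),
    largest_meal = plot_largest_meal_hist(object),
    pct_before = plot_pct_before_hist(object)
  )
}
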