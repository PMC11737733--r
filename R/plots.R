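# ggplot2 views of the diagnostic result tables.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot stratified incidence rates
#'
#' Rate per 1000 person-years against calendar year, coloured by sex and
#' faceted by age band, using the fully stratified rows of an
#' [incidence_rates()] result (marginal rows are dropped from the plot).
#'
#' @param object Output of [incidence_rates()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.pd_incidence <- function(object, ...) {
  dat <- dplyr::filter(object, !is.na(.data$calendar_year))
  if (all(is.na(dat$sex))) dat$sex <- "all"
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$calendar_year,
                                         y = .data$rate_per_1000,
                                         colour = .data$sex)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Calendar year", y = "Incidence per 1000 person-years",
                  colour = "Sex")
  if (!all(is.na(dat$age_group))) {
    p <- p + ggplot2::facet_wrap(~age_group)
  }
  p
}

#' Plot covariate balance between two cohorts
#'
#' Prevalence scatter (comparator vs target) per window; points far off the
#' diagonal have large standardized mean differences. The conventional
#' |SMD| > 0.1 imbalance threshold is highlighted.
#'
#' @param object Output of [compare_characterizations()].
#' @param smd_threshold Highlight threshold on |SMD|.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.pd_balance <- function(object, smd_threshold = 0.1, ...) {
  dat <- dplyr::mutate(
    object,
    imbalance = dplyr::case_when(
      is.na(.data$smd) ~ "undefined",
      abs(.data$smd) > smd_threshold ~ sprintf("|SMD| > %.2g", smd_threshold),
      TRUE ~ sprintf("|SMD| <= %.2g", smd_threshold)
    ),
    window = paste(.data$window_start, "to", .data$window_end)
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$p_comparator, y = .data$p_target,
                                    colour = .data$imbalance)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::facet_wrap(~window) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Prevalence (comparator)", y = "Prevalence (target)",
                  colour = NULL)
}

#' Plot time distributions around cohort entry
#'
#' Median and interquartile/decile spans of the three standard durations.
#'
#' @param object Output of [time_distributions()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.pd_time_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$measure, y = .data$median)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$p10, ymax = .data$p90),
                            linewidth = 0.4, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$p25, ymax = .data$p75)) +
    ggplot2::facet_wrap(~cohort_id) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Days")
}

#' Plot inclusion-rule attrition
#'
#' @param x A `cohort_instantiation` or its attrition tibble.
#' @return A ggplot of remaining subjects per sequential rule.
#' @export
plot_attrition <- function(x) {
  att <- if (inherits(x, "cohort_instantiation")) x$attrition else as_tibble(x)
  att <- dplyr::mutate(att, label = paste0(.data$rule_sequence, ": ", .data$rule_name))
  ggplot2::ggplot(att, ggplot2::aes(x = stats::reorder(.data$label, -.data$rule_sequence),
                                    y = .data$remaining_subjects)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~cohort_id, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Remaining subjects")
}
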