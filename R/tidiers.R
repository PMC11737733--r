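# broom-style accessors for fitted/constructed objects.

#' Tidy a cohort instantiation into its attrition table
#'
#' @param x A `cohort_instantiation`.
#' @param ... Ignored.
#' @return The attrition tibble (`cohort_id`, `rule_sequence`, `rule_name`,
#'   `remaining_entries`, `remaining_subjects`).
#' @export
tidy.cohort_instantiation <- function(x, ...) {
  x$attrition
}

#' One-row summary of a cohort instantiation
#'
#' @param x A `cohort_instantiation`.
#' @param ... Ignored.
#' @return Tibble with `cohort_id`, `name`, `entry_count`, `subject_count`,
#'   `n_rules`.
#' @export
glance.cohort_instantiation <- function(x, ...) {
  tibble(
    cohort_id = x$cohort_id, name = x$name,
    entry_count = nrow(x$entries),
    subject_count = n_distinct(x$entries$subject_id),
    n_rules = max(x$attrition$rule_sequence)
  )
}

#' Tidy a diagnostics bundle into a per-table summary
#'
#' @param x A `diagnostics_bundle`.
#' @param ... Ignored.
#' @return Tibble `table`, `n_rows`.
#' @export
tidy.diagnostics_bundle <- function(x, ...) {
  tibble(table = names(x$tables),
         n_rows = purrr::map_int(x$tables, nrow))
}

#' One-row summary of a diagnostics bundle
#'
#' @param x A `diagnostics_bundle`.
#' @param ... Ignored.
#' @return Tibble with `n_sources`, `n_tables`, `min_cell_count`, `censored`.
#' @export
glance.diagnostics_bundle <- function(x, ...) {
  tibble(
    n_sources = length(unique(x$metadata$source_name)),
    n_tables = length(x$tables),
    min_cell_count = x$min_cell_count,
    censored = isTRUE(attr(x, "censored"))
  )
}
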