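# The file-based results model: named diagnostic tables, minimum-cell-count
# censoring, CSV export with a manifest, and multi-source merge.

# Declared schema of every results table: column name -> readr type letter,
# plus which columns are person/entry counts (censorable) and which derived
# quantities must be suppressed alongside a censored count.
pd_schema <- function() {
  list(
    cohort = list(
      cols = c(source_name = "c", cohort_id = "i", cohort_name = "c",
               definition_digest = "c"),
      counts = character(), derived = character()
    ),
    cohort_count = list(
      cols = c(source_name = "c", cohort_id = "i", entry_count = "i",
               subject_count = "i"),
      counts = c("entry_count", "subject_count"), derived = character()
    ),
    attrition = list(
      cols = c(source_name = "c", cohort_id = "i", rule_sequence = "i",
               rule_name = "c", remaining_entries = "i", remaining_subjects = "i"),
      counts = c("remaining_entries", "remaining_subjects"), derived = character()
    ),
    incidence_rate = list(
      cols = c(source_name = "c", cohort_id = "i", age_group = "c", sex = "c",
               calendar_year = "i", cases = "i", person_years = "d",
               rate_per_1000 = "d"),
      counts = "cases", derived = "rate_per_1000"
    ),
    time_distribution = list(
      cols = c(source_name = "c", cohort_id = "i", measure = "c", n = "i",
               mean = "d", sd = "d", min = "d", p10 = "d", p25 = "d",
               median = "d", p75 = "d", p90 = "d", max = "d"),
      counts = "n",
      derived = c("mean", "sd", "min", "p10", "p25", "median", "p75", "p90", "max")
    ),
    index_event_breakdown = list(
      cols = c(source_name = "c", cohort_id = "i", concept_id = "i",
               concept_name = "c", entry_count = "i", subject_count = "i"),
      counts = c("entry_count", "subject_count"), derived = character()
    ),
    visit_context = list(
      cols = c(source_name = "c", cohort_id = "i", visit_category = "c",
               context = "c", subject_count = "i"),
      counts = "subject_count", derived = character()
    ),
    cohort_overlap = list(
      cols = c(source_name = "c", cohort_id_a = "i", cohort_id_b = "i",
               n_both = "i", n_only_a = "i", n_only_b = "i"),
      counts = c("n_both", "n_only_a", "n_only_b"), derived = character()
    ),
    characterization = list(
      cols = c(source_name = "c", cohort_id = "i", window_start = "d",
               window_end = "d", covariate_type = "c", concept_id = "i",
               covariate_name = "c", n_subjects = "i", proportion = "d"),
      counts = "n_subjects", derived = "proportion"
    ),
    balance = list(
      cols = c(source_name = "c", cohort_id_target = "i",
               cohort_id_comparator = "i", window_start = "d", window_end = "d",
               covariate_type = "c", concept_id = "i", covariate_name = "c",
               p_target = "d", p_comparator = "d", smd = "d"),
      counts = character(), derived = character()
    ),
    metadata = list(
      cols = c(source_name = "c", schema_version = "c", tool_version = "c",
               min_cell_count = "i"),
      counts = character(), derived = character()
    )
  )
}

readr_cols_for <- function(spec) {
  conv <- list(c = readr::col_character(), i = readr::col_integer(),
               d = readr::col_double())
  do.call(readr::cols, c(purrr::map(as.list(spec$cols), ~ conv[[.x]]),
                         list(.default = readr::col_character())))
}

# Coerce a table to its declared schema: add missing columns as NA, order
# columns, drop extras. Forbids person-level identifier columns.
conform_table <- function(tab, name, source_name) {
  spec <- pd_schema()[[name]]
  if (is.null(spec)) abort(sprintf("Unknown results table '%s'", name))
  tab <- as_tibble(tab)
  if (any(c("subject_id", "person_id") %in% names(tab))) {
    abort(sprintf(
      "Table '%s' contains a person-level identifier column; subject ids never leave the diagnostics boundary.",
      name
    ))
  }
  if (!"source_name" %in% names(tab)) tab$source_name <- source_name
  for (col in names(spec$cols)) {
    if (!col %in% names(tab)) {
      tab[[col]] <- switch(spec$cols[[col]], c = NA_character_,
                           i = NA_integer_, d = NA_real_)
    }
  }
  tab[, names(spec$cols)]
}

#' Assemble a diagnostics bundle
#'
#' A bundle is the in-memory form of the results model: one named tibble per
#' diagnostic family plus run metadata and the censoring policy. Tables are
#' conformed to the declared schema; person-level identifier columns are
#' rejected.
#'
#' @param source_name Data source label (stamped into every table row).
#' @param tables Named list of result tibbles; names must be results-model
#'   table names (`cohort`, `cohort_count`, `attrition`, `incidence_rate`,
#'   `time_distribution`, `index_event_breakdown`, `visit_context`,
#'   `cohort_overlap`, `characterization`, `balance`).
#' @param min_cell_count Censoring policy: nonzero counts below this are
#'   replaced by the negative threshold before export; 0 disables censoring.
#' @return A `diagnostics_bundle`.
#' @export
diagnostics_bundle <- function(source_name, tables, min_cell_count = 5L) {
  stopifnot(min_cell_count >= 0)
  allowed <- setdiff(names(pd_schema()), "metadata")
  bad <- setdiff(names(tables), allowed)
  if (length(bad) > 0) {
    abort(sprintf("Unknown results table(s): %s", paste(bad, collapse = ", ")))
  }
  tables <- purrr::imap(tables, ~ conform_table(.x, .y, source_name))
  structure(
    list(
      source_name = source_name,
      tables = tables,
      metadata = tibble(
        source_name = source_name,
        schema_version = PHENODIAG_SCHEMA_VERSION,
        tool_version = as.character(packageVersion("phenodiag")),
        min_cell_count = as.integer(min_cell_count)
      ),
      run_timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      min_cell_count = as.integer(min_cell_count)
    ),
    class = "diagnostics_bundle",
    censored = FALSE
  )
}

#' @export
print.diagnostics_bundle <- function(x, ...) {
  cat(sprintf("<diagnostics_bundle '%s'%s>: %d table(s), min_cell_count=%d\n",
              paste(unique(x$metadata$source_name), collapse = "+"),
              if (isTRUE(attr(x, "censored"))) " (censored)" else "",
              length(x$tables), x$min_cell_count))
  for (nm in names(x$tables)) {
    cat(sprintf("  %-22s %d row(s)\n", nm, nrow(x$tables[[nm]])))
  }
  invisible(x)
}

#' Apply minimum-cell-count censoring to a bundle
#'
#' Every person/entry count `c` with `0 < c < min_cell_count` is replaced by
#' the sentinel `-min_cell_count` (negative threshold, so consumers can
#' distinguish "censored" from "zero" and recover the policy); derived
#' quantities computed from a censored count (proportions, rates, summary
#' statistics) are suppressed to `NA` in the same row rather than recomputed,
#' preventing back-calculation. Zero counts pass through. Idempotent.
#'
#' @param bundle A [diagnostics_bundle].
#' @param min_cell_count Overrides the bundle's policy when given.
#' @return The censored bundle.
#' @export
censor <- function(bundle, min_cell_count = NULL) {
  stopifnot(inherits(bundle, "diagnostics_bundle"))
  k <- as.integer(min_cell_count %||% bundle$min_cell_count)
  stopifnot(k >= 0)
  schema <- pd_schema()
  bundle$tables <- purrr::imap(bundle$tables, function(tab, name) {
    spec <- schema[[name]]
    if (k == 0 || length(spec$counts) == 0 || nrow(tab) == 0) return(tab)
    hit <- rep(FALSE, nrow(tab))
    for (col in spec$counts) {
      cc <- tab[[col]]
      mask <- !is.na(cc) & cc > 0 & cc < k
      hit <- hit | mask
      cc[mask] <- -k
      tab[[col]] <- cc
    }
    for (col in spec$derived) {
      tab[[col]][hit] <- NA
    }
    tab
  })
  bundle$min_cell_count <- k
  bundle$metadata$min_cell_count <- k
  attr(bundle, "censored") <- TRUE
  bundle
}

round_for_export <- function(tab, name) {
  spec <- pd_schema()[[name]]
  for (col in names(spec$cols)[spec$cols == "d"]) {
    tab[[col]] <- signif(tab[[col]], 5)
  }
  tab
}

#' Export a bundle to a directory of CSV files
#'
#' One headered CSV per table in stable column order (plus `metadata.csv`),
#' dates ISO-8601, derived quantities rounded to 5 significant digits, and a
#' JSON manifest listing file names, row counts and an md5 content digest per
#' file. Files are plain, unencrypted, human-auditable text. Exporting an
#' uncensored bundle under a nonzero policy is refused.
#'
#' @param bundle A censored [diagnostics_bundle].
#' @param directory Output directory (created if needed).
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
export_bundle <- function(bundle, directory) {
  stopifnot(inherits(bundle, "diagnostics_bundle"))
  if (bundle$min_cell_count > 0 && !isTRUE(attr(bundle, "censored"))) {
    abort("Refusing to export an uncensored bundle under a nonzero minimum-cell-count policy; call censor() first.")
  }
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  write_one <- function(tab, name) {
    path <- file.path(directory, paste0(name, ".csv"))
    readr::write_csv(round_for_export(tab, name), path, na = "")
    files[[length(files) + 1]] <<- list(
      file = basename(path), table = name, n_rows = nrow(tab),
      md5 = unname(tools::md5sum(path))
    )
  }
  for (nm in names(bundle$tables)) write_one(bundle$tables[[nm]], nm)
  write_one(bundle$metadata, "metadata")
  manifest <- list(
    schema_version = PHENODIAG_SCHEMA_VERSION,
    source_name = unique(bundle$metadata$source_name),
    min_cell_count = bundle$min_cell_count,
    files = files
  )
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a bundle back from an exported directory
#'
#' @param directory A directory produced by [export_bundle()].
#' @return A `diagnostics_bundle` (marked censored; the policy is recovered
#'   from the metadata table).
#' @export
read_bundle <- function(directory) {
  mpath <- file.path(directory, "manifest.json")
  if (!file.exists(mpath)) abort(sprintf("No manifest.json in %s", directory))
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  schema <- pd_schema()
  meta <- readr::read_csv(file.path(directory, "metadata.csv"),
                          col_types = readr_cols_for(schema$metadata),
                          progress = FALSE, na = "")
  tables <- list()
  for (f in manifest$files$table) {
    if (f == "metadata") next
    tables[[f]] <- readr::read_csv(
      file.path(directory, paste0(f, ".csv")),
      col_types = readr_cols_for(schema[[f]]), progress = FALSE, na = ""
    )
  }
  b <- structure(
    list(
      source_name = manifest$source_name,
      tables = tables,
      metadata = meta,
      min_cell_count = as.integer(manifest$min_cell_count)
    ),
    class = "diagnostics_bundle",
    censored = TRUE
  )
  b
}

#' Merge bundles from multiple data sources
#'
#' Row-wise concatenation keyed by (`source_name`, `cohort_id`); no
#' cross-source aggregation is performed. Schema versions must match and
#' source names must be distinct.
#'
#' @param bundles List of `diagnostics_bundle` objects (or directories to
#'   read with [read_bundle()]).
#' @return The merged `diagnostics_bundle`.
#' @export
merge_bundles <- function(bundles) {
  bundles <- purrr::map(bundles, function(b) {
    if (is.character(b)) read_bundle(b) else b
  })
  stopifnot(length(bundles) >= 1)
  versions <- unique(purrr::map_chr(bundles, ~ unique(.x$metadata$schema_version)))
  if (length(versions) > 1) {
    abort(sprintf("Schema version mismatch across bundles: %s",
                  paste(versions, collapse = " vs ")))
  }
  srcs <- purrr::map(bundles, ~ unique(.x$metadata$source_name))
  flat <- unlist(srcs)
  if (anyDuplicated(flat)) {
    abort(sprintf("Duplicate source_name(s) in merge: %s",
                  paste(unique(flat[duplicated(flat)]), collapse = ", ")))
  }
  table_names <- unique(unlist(purrr::map(bundles, ~ names(.x$tables))))
  tables <- purrr::map(setNames(table_names, table_names), function(nm) {
    bind_rows(purrr::map(bundles, ~ .x$tables[[nm]]))
  })
  structure(
    list(
      source_name = flat,
      tables = tables,
      metadata = bind_rows(purrr::map(bundles, "metadata")),
      min_cell_count = max(purrr::map_int(bundles, "min_cell_count"))
    ),
    class = "diagnostics_bundle",
    censored = all(purrr::map_lgl(bundles, ~ isTRUE(attr(.x, "censored")) ||
                                    .x$min_cell_count == 0))
  )
}
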