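# CDM store: load, validate and index OMOP-shaped patient-level and
# vocabulary tables, exposing a unified clinical-event stream.

# Mapping from OMOP v5.3 domain tables to the unified event view.
OMOP_EVENT_TABLES <- list(
  condition_occurrence = list(
    domain = "condition", concept = "condition_concept_id",
    start = "condition_start_date", end = "condition_end_date"
  ),
  drug_exposure = list(
    domain = "drug", concept = "drug_concept_id",
    start = "drug_exposure_start_date", end = "drug_exposure_end_date"
  ),
  procedure_occurrence = list(
    domain = "procedure", concept = "procedure_concept_id",
    start = "procedure_date", end = NA_character_
  ),
  measurement = list(
    domain = "measurement", concept = "measurement_concept_id",
    start = "measurement_date", end = NA_character_
  ),
  observation = list(
    domain = "observation", concept = "observation_concept_id",
    start = "observation_date", end = NA_character_
  )
)

EVENT_DOMAINS <- c("condition", "drug", "procedure", "measurement", "observation")
VISIT_CATEGORIES <- c("inpatient", "outpatient", "emergency", "other")
SEX_LEVELS <- c("FEMALE", "MALE", "OTHER")

# OMOP gender_concept_id conventions.
GENDER_CONCEPT_MAP <- c("8532" = "FEMALE", "8507" = "MALE")

#' Construct a CDM store from in-memory tables
#'
#' Builds a validated `cdm_store` from tibbles already in the unified shape
#' (see Details). [load_cdm()] is the file-based front end that converts raw
#' OMOP v5.3 tables into this shape. Overlapping or abutting observation
#' periods per person are merged into a canonical non-overlapping set; the
#' raw rows are retained in `attr(store, "raw_observation_periods")` for
#' audit. The unified event view is append-ordered and carries a stable
#' surrogate `event_id` for reproducible tie-breaking.
#'
#' @details Expected columns:
#' * `persons`: `person_id`, `sex` (`FEMALE`/`MALE`/`OTHER`), `year_of_birth`
#'   (integer, may be `NA`).
#' * `observation_periods`: `person_id`, `start_date`, `end_date` (Date).
#' * `clinical_events`: `person_id`, `concept_id`, `domain`, `event_date`,
#'   `end_date` (Date or `NA`).
#' * `visits`: `person_id`, `visit_category`, `start_date`, `end_date`.
#' * `concepts`: `concept_id`, `concept_name`, `domain_id`, `vocabulary_id`.
#' * `concept_ancestors`: `ancestor_concept_id`, `descendant_concept_id`.
#'
#' @param persons,observation_periods,clinical_events,visits,concepts,concept_ancestors
#'   Data frames as described in Details; event/visit/vocabulary tables may be
#'   omitted (empty tables are substituted).
#' @param source_name Free-text label identifying the data source.
#' @return An object of class `cdm_store`: a named list of tibbles with
#'   normalized observation periods and an append-ordered event view.
#' @export
cdm_store <- function(persons, observation_periods,
                      clinical_events = NULL, visits = NULL,
                      concepts = NULL, concept_ancestors = NULL,
                      source_name = "source") {
  persons <- as_tibble(persons)
  stopifnot(all(c("person_id", "sex", "year_of_birth") %in% names(persons)))
  if (anyDuplicated(persons$person_id)) {
    dup <- persons$person_id[duplicated(persons$person_id)]
    abort(sprintf("Duplicate person_id(s) in person table: %s",
                  paste(unique(head(dup, 5)), collapse = ", ")))
  }
  persons$person_id <- as.integer(persons$person_id)
  persons$sex <- toupper(as.character(persons$sex))
  persons$sex[!persons$sex %in% SEX_LEVELS] <- "OTHER"
  persons$year_of_birth <- as.integer(persons$year_of_birth)

  observation_periods <- as_tibble(observation_periods)
  stopifnot(all(c("person_id", "start_date", "end_date") %in% names(observation_periods)))
  observation_periods$person_id <- as.integer(observation_periods$person_id)
  observation_periods$start_date <-
    parse_iso_dates(observation_periods$start_date, "observation_period", "start_date")
  observation_periods$end_date <-
    parse_iso_dates(observation_periods$end_date, "observation_period", "end_date")

  empty_events <- tibble(
    person_id = integer(), concept_id = integer(),
    domain = character(), event_date = as.Date(character()),
    end_date = as.Date(character())
  )
  clinical_events <- if (is.null(clinical_events)) empty_events else as_tibble(clinical_events)
  if (!"end_date" %in% names(clinical_events)) clinical_events$end_date <- as.Date(NA)
  clinical_events <- clinical_events[, names(empty_events)]
  clinical_events$person_id <- as.integer(clinical_events$person_id)
  clinical_events$concept_id <- as.integer(clinical_events$concept_id)
  clinical_events$event_date <-
    parse_iso_dates(clinical_events$event_date, "clinical_event", "event_date")
  clinical_events$end_date <-
    parse_iso_dates(clinical_events$end_date, "clinical_event", "end_date")
  bad_dom <- setdiff(unique(clinical_events$domain), EVENT_DOMAINS)
  if (length(bad_dom) > 0) {
    abort(sprintf("Unknown event domain(s): %s", paste(bad_dom, collapse = ", ")))
  }

  empty_visits <- tibble(
    person_id = integer(), visit_category = character(),
    start_date = as.Date(character()), end_date = as.Date(character())
  )
  visits <- if (is.null(visits)) empty_visits else as_tibble(visits)[, names(empty_visits)]
  visits$person_id <- as.integer(visits$person_id)
  visits$visit_category <- tolower(as.character(visits$visit_category))
  visits$visit_category[!visits$visit_category %in% VISIT_CATEGORIES] <- "other"
  visits$start_date <- parse_iso_dates(visits$start_date, "visit", "start_date")
  visits$end_date <- parse_iso_dates(visits$end_date, "visit", "end_date")

  empty_concepts <- tibble(
    concept_id = integer(), concept_name = character(),
    domain_id = character(), vocabulary_id = character()
  )
  concepts <- if (is.null(concepts)) empty_concepts else as_tibble(concepts)[, names(empty_concepts)]
  concepts$concept_id <- as.integer(concepts$concept_id)

  empty_anc <- tibble(ancestor_concept_id = integer(), descendant_concept_id = integer())
  concept_ancestors <-
    if (is.null(concept_ancestors)) empty_anc else as_tibble(concept_ancestors)[, names(empty_anc)]
  concept_ancestors$ancestor_concept_id <- as.integer(concept_ancestors$ancestor_concept_id)
  concept_ancestors$descendant_concept_id <- as.integer(concept_ancestors$descendant_concept_id)

  # Referential integrity (fatal at construction).
  check_fk <- function(ids, table) {
    missing <- setdiff(unique(ids), persons$person_id)
    if (length(missing) > 0) {
      abort(sprintf(
        "Referential-integrity error: %s references person_id(s) absent from person table: %s",
        table, paste(head(missing, 5), collapse = ", ")
      ))
    }
  }
  check_fk(observation_periods$person_id, "observation_period")
  check_fk(clinical_events$person_id, "clinical_event")
  check_fk(visits$person_id, "visit")

  bad_op <- which(observation_periods$end_date < observation_periods$start_date)
  if (length(bad_op) > 0) {
    abort(sprintf("observation_period end before start at row(s) %s",
                  paste(head(bad_op, 5), collapse = ", ")))
  }

  raw_periods <- observation_periods
  observation_periods <- normalize_periods(observation_periods)

  clinical_events <- clinical_events %>%
    mutate(event_id = row_number(), .before = 1)

  store <- structure(
    list(
      source_name = as.character(source_name),
      persons = persons,
      observation_periods = observation_periods,
      clinical_events = clinical_events,
      visits = visits,
      concepts = concepts,
      concept_ancestors = concept_ancestors
    ),
    class = "cdm_store"
  )
  attr(store, "raw_observation_periods") <- raw_periods
  n_noyob <- sum(is.na(persons$year_of_birth))
  if (n_noyob > 0) {
    inform(sprintf(
      "%d person(s) lack year_of_birth and will be excluded from age-stratified outputs.",
      n_noyob
    ))
  }
  store
}

# Merge overlapping/abutting periods per person (gap <= 0 days).
normalize_periods <- function(periods) {
  if (nrow(periods) == 0) return(as_tibble(periods))
  periods %>%
    arrange(.data$person_id, .data$start_date, .data$end_date) %>%
    group_by(.data$person_id) %>%
    dplyr::reframe({
      m <- merge_day_intervals(.data$start_date, .data$end_date, gap_days = 0L)
      tibble(start_date = m$start, end_date = m$end)
    }) %>%
    as_tibble()
}

#' @export
print.cdm_store <- function(x, ...) {
  cat(sprintf(
    "<cdm_store '%s'>: %d persons, %d observation periods, %d events, %d visits, %d concepts\n",
    x$source_name, nrow(x$persons), nrow(x$observation_periods),
    nrow(x$clinical_events), nrow(x$visits), nrow(x$concepts)
  ))
  invisible(x)
}

#' Load a CDM store from a directory of OMOP-shaped CSV or Parquet files
#'
#' Reads one file per CDM table (`person`, `observation_period`, the event
#' domain tables, `visit_occurrence`, `concept`, `concept_ancestor`) from
#' `path`, in OMOP v5.3 column naming, and merges the event domain tables
#' into the unified clinical-event view with domain labels preserved.
#' A mapping config (`column_map` or JSON file `table_map.json` in `path`)
#' may rename tables/columns of a near-OMOP dialect.
#'
#' @param path Directory containing one `<table>.csv` (or `.parquet`) per table.
#' @param source_name Label for the data source; defaults to the directory name.
#' @param column_map Optional nested list `list(<table> = c(<omop_col> = <actual_col>))`
#'   renaming columns of a near-OMOP dialect.
#' @return A validated [cdm_store].
#' @export
load_cdm <- function(path, source_name = basename(normalizePath(path)),
                     column_map = NULL) {
  if (!dir.exists(path)) abort(sprintf("CDM directory not found: %s", path))
  map_file <- file.path(path, "table_map.json")
  if (is.null(column_map) && file.exists(map_file)) {
    column_map <- jsonlite::read_json(map_file, simplifyVector = TRUE)
  }

  read_table <- function(name, required = FALSE) {
    csv <- file.path(path, paste0(name, ".csv"))
    pq <- file.path(path, paste0(name, ".parquet"))
    tab <- if (file.exists(csv)) {
      readr::read_csv(csv, show_col_types = FALSE, progress = FALSE,
                      col_types = readr::cols(.default = readr::col_character()))
    } else if (file.exists(pq)) {
      if (!requireNamespace("arrow", quietly = TRUE)) {
        abort("Parquet input requires the 'arrow' package.")
      }
      arrow::read_parquet(pq)
    } else if (required) {
      abort(sprintf("Mandatory CDM table '%s' not found in %s", name, path))
    } else {
      NULL
    }
    if (!is.null(tab) && !is.null(column_map[[name]])) {
      cm <- unlist(column_map[[name]])
      for (omop_col in names(cm)) {
        names(tab)[names(tab) == cm[[omop_col]]] <- omop_col
      }
    }
    tab
  }

  person <- read_table("person", required = TRUE)
  op <- read_table("observation_period", required = TRUE)
  concept <- read_table("concept", required = TRUE)
  ancestor <- read_table("concept_ancestor")
  visit <- read_table("visit_occurrence")

  events <- list()
  for (tab_name in names(OMOP_EVENT_TABLES)) {
    spec <- OMOP_EVENT_TABLES[[tab_name]]
    raw <- read_table(tab_name)
    if (is.null(raw)) next
    ev <- tibble(
      person_id = as.integer(raw$person_id),
      concept_id = as.integer(raw[[spec$concept]]),
      domain = spec$domain,
      event_date = parse_iso_dates(raw[[spec$start]], tab_name, spec$start),
      end_date = if (!is.na(spec$end) && spec$end %in% names(raw)) {
        parse_iso_dates(raw[[spec$end]], tab_name, spec$end)
      } else {
        as.Date(NA)
      }
    )
    events[[tab_name]] <- ev
  }
  if (length(events) == 0) {
    abort(sprintf("No event domain table found in %s (need at least one of: %s)",
                  path, paste(names(OMOP_EVENT_TABLES), collapse = ", ")))
  }
  clinical_events <- bind_rows(events)

  sex <- GENDER_CONCEPT_MAP[as.character(person$gender_concept_id)]
  sex[is.na(sex)] <- "OTHER"
  persons <- tibble(
    person_id = as.integer(person$person_id),
    sex = unname(sex),
    year_of_birth = suppressWarnings(as.integer(person$year_of_birth))
  )

  visits <- NULL
  if (!is.null(visit)) {
    vc <- c("9201" = "inpatient", "9202" = "outpatient", "9203" = "emergency")
    cat_raw <- vc[as.character(visit$visit_concept_id)]
    cat_raw[is.na(cat_raw)] <- "other"
    visits <- tibble(
      person_id = as.integer(visit$person_id),
      visit_category = unname(cat_raw),
      start_date = parse_iso_dates(visit$visit_start_date, "visit_occurrence", "visit_start_date"),
      end_date = parse_iso_dates(visit$visit_end_date, "visit_occurrence", "visit_end_date")
    )
  }

  concepts <- tibble(
    concept_id = as.integer(concept$concept_id),
    concept_name = as.character(concept$concept_name),
    domain_id = as.character(concept$domain_id),
    vocabulary_id = as.character(concept$vocabulary_id)
  )
  ancestors <- if (is.null(ancestor)) NULL else tibble(
    ancestor_concept_id = as.integer(ancestor$ancestor_concept_id),
    descendant_concept_id = as.integer(ancestor$descendant_concept_id)
  )

  cdm_store(
    persons = persons,
    observation_periods = tibble(
      person_id = as.integer(op$person_id),
      start_date = parse_iso_dates(op$observation_period_start_date,
                                   "observation_period", "observation_period_start_date"),
      end_date = parse_iso_dates(op$observation_period_end_date,
                                 "observation_period", "observation_period_end_date")
    ),
    clinical_events = clinical_events,
    visits = visits,
    concepts = concepts,
    concept_ancestors = ancestors,
    source_name = source_name
  )
}

#' Write a CDM store to a directory in its OMOP v5.3 file layout
#'
#' The on-disk form round-trips through [load_cdm()]: writing and reloading
#' yields an identical store (normalized periods, same event view order).
#'
#' @param store A [cdm_store].
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_cdm <- function(store, path) {
  stopifnot(inherits(store, "cdm_store"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  gender_inv <- c(FEMALE = 8532L, MALE = 8507L, OTHER = 0L)
  readr::write_csv(tibble(
    person_id = store$persons$person_id,
    gender_concept_id = unname(gender_inv[store$persons$sex]),
    year_of_birth = store$persons$year_of_birth
  ), file.path(path, "person.csv"))
  readr::write_csv(tibble(
    person_id = store$observation_periods$person_id,
    observation_period_start_date = store$observation_periods$start_date,
    observation_period_end_date = store$observation_periods$end_date
  ), file.path(path, "observation_period.csv"))
  ev <- store$clinical_events
  for (tab_name in names(OMOP_EVENT_TABLES)) {
    spec <- OMOP_EVENT_TABLES[[tab_name]]
    sub <- ev[ev$domain == spec$domain, ]
    if (nrow(sub) == 0) next
    out <- tibble(person_id = sub$person_id)
    out[[spec$concept]] <- sub$concept_id
    out[[spec$start]] <- sub$event_date
    if (!is.na(spec$end)) out[[spec$end]] <- sub$end_date
    readr::write_csv(out, file.path(path, paste0(tab_name, ".csv")))
  }
  if (nrow(store$visits) > 0) {
    vis_inv <- c(inpatient = 9201L, outpatient = 9202L, emergency = 9203L, other = 0L)
    readr::write_csv(tibble(
      person_id = store$visits$person_id,
      visit_concept_id = unname(vis_inv[store$visits$visit_category]),
      visit_start_date = store$visits$start_date,
      visit_end_date = store$visits$end_date
    ), file.path(path, "visit_occurrence.csv"))
  }
  readr::write_csv(store$concepts, file.path(path, "concept.csv"))
  if (nrow(store$concept_ancestors) > 0) {
    readr::write_csv(store$concept_ancestors, file.path(path, "concept_ancestor.csv"))
  }
  invisible(path)
}

#' Normalized observation intervals for one person
#'
#' @param store A [cdm_store].
#' @param person_id Scalar person identifier.
#' @return Tibble with `start_date`, `end_date`: the person's merged,
#'   non-overlapping, chronologically sorted observation periods (zero rows
#'   if the person has no periods).
#' @export
observed_interval <- function(store, person_id) {
  stopifnot(inherits(store, "cdm_store"))
  if (!person_id %in% store$persons$person_id) {
    abort(sprintf("Person %s not found in store '%s'", person_id, store$source_name))
  }
  store$observation_periods %>%
    filter(.data$person_id == !!as.integer(person_id)) %>%
    select("start_date", "end_date")
}

#' Validate a CDM store and report findings
#'
#' Enumerates invariant violations as data rather than raising: an empty
#' report means all invariants hold. Severities are `"error"` (structurally
#' wrong) and `"warning"` (suspicious but usable, e.g. an event dated outside
#' all of its person's observation periods).
#'
#' @param store A [cdm_store].
#' @return Tibble with columns `severity`, `table`, `finding`, `n_rows`.
#' @export
validate_cdm <- function(store) {
  stopifnot(inherits(store, "cdm_store"))
  findings <- list()
  add <- function(severity, table, finding, n_rows) {
    findings[[length(findings) + 1]] <<-
      tibble(severity = severity, table = table, finding = finding, n_rows = as.integer(n_rows))
  }

  raw <- attr(store, "raw_observation_periods")
  if (!is.null(raw)) {
    bad <- sum(raw$end_date < raw$start_date, na.rm = TRUE)
    if (bad > 0) add("error", "observation_period", "end_date before start_date", bad)
  }

  max_year <- suppressWarnings(max(as.integer(format(store$observation_periods$end_date, "%Y"))))
  if (is.finite(max_year)) {
    bad <- sum(store$persons$year_of_birth > max_year, na.rm = TRUE)
    if (bad > 0) add("error", "person", "year_of_birth after latest observation year", bad)
  }

  ev <- store$clinical_events
  if (nrow(ev) > 0) {
    bad <- sum(!is.na(ev$end_date) & ev$end_date < ev$event_date)
    if (bad > 0) add("error", "clinical_event", "end_date before event_date", bad)
    cov <- ev %>%
      left_join(store$observation_periods, by = "person_id",
                relationship = "many-to-many") %>%
      mutate(inside = !is.na(.data$start_date) &
               .data$event_date >= .data$start_date &
               .data$event_date <= .data$end_date.y) %>%
      group_by(.data$event_id) %>%
      summarise(inside = any(.data$inside), .groups = "drop")
    n_out <- sum(!cov$inside)
    if (n_out > 0) {
      add("warning", "clinical_event",
          "event dated outside all observation periods of its person", n_out)
    }
  }

  vis <- store$visits
  if (nrow(vis) > 0) {
    bad <- sum(vis$end_date < vis$start_date)
    if (bad > 0) add("error", "visit", "end_date before start_date", bad)
  }

  if (length(findings) == 0) {
    tibble(severity = character(), table = character(),
           finding = character(), n_rows = integer())
  } else {
    bind_rows(findings)
  }
}
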