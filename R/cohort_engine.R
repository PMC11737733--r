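# Declarative phenotype-algorithm (cohort) definitions and their
# instantiation against a CDM store.

#' Create a cohort definition
#'
#' A cohort definition is a declarative phenotype algorithm: concept sets,
#' entry events (the earliest qualifying event across all listed entry events
#' becomes the index date), a prior continuous-observation requirement
#' (washout), an ordered list of inclusion rules evaluated relative to the
#' index date, and an exit strategy.
#'
#' @param cohort_id Integer cohort identifier (unique within a run).
#' @param name Cohort name.
#' @param concept_sets List of [concept_set] objects.
#' @param entry_events List of entry events, each
#'   `list(domain =, concept_set_id =, occurrence = "first_ever"|"all")`.
#'   `first_ever` restricts candidates to the subject's earliest event of the
#'   concept set in the whole store (before washout filtering).
#' @param prior_observation_days Required days of continuous observation
#'   before the index date (the enclosing normalized observation period must
#'   start at least this many days before index).
#' @param inclusion_rules Ordered list of rules, each
#'   `list(name =, domain =, concept_set_id =, window = c(start, end),
#'   occurrence_count = list(comparator = "at_least"|"at_most"|"exactly", n =))`.
#'   Windows are closed intervals in days relative to index (day 0 = index);
#'   `-Inf`/`Inf` encode unbounded offsets. Exclusion criteria are expressed
#'   as `at_most 0` rules.
#' @param exit Exit strategy: `list(strategy = "end_of_observation")` or
#'   `list(strategy = "fixed_offset", days =)` (capped at the observation
#'   period end).
#' @return A `cohort_definition` object.
#' @export
cohort_definition <- function(cohort_id, name, concept_sets, entry_events,
                              prior_observation_days = 0L,
                              inclusion_rules = list(),
                              exit = list(strategy = "end_of_observation")) {
  stopifnot(prior_observation_days >= 0)
  cs_ids <- purrr::map_int(concept_sets, "concept_set_id")
  if (anyDuplicated(cs_ids)) abort("concept_set_ids must be distinct within a definition")
  ref_ids <- c(
    purrr::map_int(entry_events, ~ as.integer(.x$concept_set_id)),
    purrr::map_int(inclusion_rules, ~ as.integer(.x$concept_set_id))
  )
  missing <- setdiff(ref_ids, cs_ids)
  if (length(missing) > 0) {
    abort(sprintf("Definition '%s' references undefined concept_set_id(s): %s",
                  name, paste(missing, collapse = ", ")))
  }
  for (r in inclusion_rules) {
    if (r$window[1] > r$window[2]) {
      abort(sprintf("Inclusion rule '%s': window start offset exceeds end offset", r$name))
    }
  }
  stopifnot(exit$strategy %in% c("end_of_observation", "fixed_offset"))
  structure(
    list(
      cohort_id = as.integer(cohort_id), name = as.character(name),
      concept_sets = setNames(concept_sets, cs_ids),
      entry_events = entry_events,
      prior_observation_days = as.integer(prior_observation_days),
      inclusion_rules = inclusion_rules,
      exit = exit
    ),
    class = "cohort_definition"
  )
}

#' @export
print.cohort_definition <- function(x, ...) {
  cat(sprintf(
    "<cohort_definition %d '%s'>: %d concept sets, %d entry events, washout %d d, %d inclusion rules, exit=%s\n",
    x$cohort_id, x$name, length(x$concept_sets), length(x$entry_events),
    x$prior_observation_days, length(x$inclusion_rules), x$exit$strategy
  ))
  invisible(x)
}

unbounded_to_num <- function(x) {
  if (is.null(x)) return(Inf)
  if (is.character(x)) {
    lx <- tolower(x)
    if (lx %in% c("inf", "+inf", "all")) return(Inf)
    if (lx %in% c("-inf")) return(-Inf)
  }
  as.numeric(x)
}

#' Read a cohort definition from its JSON document
#'
#' The schema (versioned, shipped with the package in `inst/extdata/*.json`)
#' mirrors [cohort_definition()]; window offsets may be `null`/"inf" for
#' unbounded.
#'
#' @param path Path to a definition JSON file.
#' @return A [cohort_definition].
#' @export
read_cohort_definition <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  concept_sets <- purrr::map(doc$concept_sets, function(cs) {
    items <- purrr::map_dfr(cs$items, function(it) {
      tibble(
        concept_id = as.integer(it$concept_id),
        include_descendants = isTRUE(it$include_descendants),
        is_excluded = isTRUE(it$is_excluded)
      )
    })
    concept_set(cs$concept_set_id, cs$name, items)
  })
  rules <- purrr::map(doc$inclusion_rules %||% list(), function(r) {
    list(
      name = r$name, domain = r$domain,
      concept_set_id = as.integer(r$concept_set_id),
      window = c(unbounded_to_num(r$window[[1]]), unbounded_to_num(r$window[[2]])),
      occurrence_count = list(
        comparator = r$occurrence_count$comparator,
        n = as.integer(r$occurrence_count$n)
      )
    )
  })
  exit <- doc$exit %||% list(strategy = "end_of_observation")
  if (identical(exit$strategy, "fixed_offset")) exit$days <- as.integer(exit$days)
  cohort_definition(
    cohort_id = doc$cohort_id, name = doc$name,
    concept_sets = concept_sets,
    entry_events = purrr::map(doc$entry_events, function(ee) {
      list(domain = ee$domain, concept_set_id = as.integer(ee$concept_set_id),
           occurrence = ee$occurrence %||% "all")
    }),
    prior_observation_days = as.integer(doc$prior_observation_days %||% 0L),
    inclusion_rules = rules,
    exit = exit
  )
}

#' Serialize a cohort definition to JSON
#'
#' @param defn A [cohort_definition].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_definition <- function(defn, path) {
  doc <- list(
    schema_version = PHENODIAG_SCHEMA_VERSION,
    cohort_id = defn$cohort_id, name = defn$name,
    concept_sets = purrr::map(unname(defn$concept_sets), function(cs) {
      list(concept_set_id = cs$concept_set_id, name = cs$name,
           items = purrr::pmap(cs$items, function(concept_id, include_descendants, is_excluded) {
             list(concept_id = concept_id, include_descendants = include_descendants,
                  is_excluded = is_excluded)
           }))
    }),
    entry_events = defn$entry_events,
    prior_observation_days = defn$prior_observation_days,
    inclusion_rules = purrr::map(defn$inclusion_rules, function(r) {
      w <- purrr::map(as.list(r$window), function(o) if (is.infinite(o)) NULL else o)
      list(name = r$name, domain = r$domain, concept_set_id = r$concept_set_id,
           window = w, occurrence_count = r$occurrence_count)
    }),
    exit = defn$exit
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(path)
}

# Events of `domain` whose concept is in the resolved set of `concept_set_id`.
matching_events <- function(store, defn, domain, concept_set_id) {
  ids <- resolve_concept_set(defn$concept_sets[[as.character(concept_set_id)]], store)
  store$clinical_events %>%
    filter(.data$domain == !!domain, .data$concept_id %in% ids)
}

#' Instantiate a cohort definition against a CDM store
#'
#' Index selection: per subject, the earliest event matching any entry event
#' that lies inside a normalized observation period starting at least
#' `prior_observation_days` before it. Inclusion rules are then applied
#' sequentially against the index date; attrition is recorded per rule
#' (rule_sequence 0 = entry events). Exit follows the definition's strategy.
#' Instantiation is fully deterministic.
#'
#' @param defn A [cohort_definition].
#' @param store A [cdm_store].
#' @return A `cohort_instantiation` object: list with `entries` (tibble
#'   `cohort_id`, `subject_id`, `cohort_start_date`, `cohort_end_date`) and
#'   `attrition` (tibble `cohort_id`, `rule_sequence`, `rule_name`,
#'   `remaining_entries`, `remaining_subjects`).
#' @export
instantiate_cohort <- function(defn, store) {
  stopifnot(inherits(defn, "cohort_definition"), inherits(store, "cdm_store"))

  candidates <- purrr::map_dfr(defn$entry_events, function(ee) {
    ev <- matching_events(store, defn, ee$domain, ee$concept_set_id)
    if (identical(ee$occurrence, "first_ever") && nrow(ev) > 0) {
      ev <- ev %>%
        group_by(.data$person_id) %>%
        slice_min(.data$event_date, n = 1, with_ties = FALSE) %>%
        ungroup()
    }
    ev
  })

  periods <- store$observation_periods
  if (nrow(candidates) > 0) {
    qualified <- candidates %>%
      inner_join(periods, by = "person_id", relationship = "many-to-many") %>%
      filter(.data$event_date >= .data$start_date,
             .data$event_date <= .data$end_date.y) %>%
      filter(as.integer(.data$event_date) - as.integer(.data$start_date) >=
               defn$prior_observation_days) %>%
      group_by(.data$person_id) %>%
      slice_min(.data$event_date, n = 1, with_ties = FALSE) %>%
      ungroup()
  } else {
    qualified <- candidates[0, ] %>%
      mutate(start_date = as.Date(character()), end_date.y = as.Date(character()))
  }

  entries <- tibble(
    cohort_id = rep(defn$cohort_id, nrow(qualified)),
    subject_id = qualified$person_id,
    cohort_start_date = qualified$event_date,
    period_start = qualified$start_date,
    period_end = if ("end_date.y" %in% names(qualified)) qualified$end_date.y else qualified$end_date
  )

  attrition <- list(tibble(
    cohort_id = defn$cohort_id, rule_sequence = 0L, rule_name = "Entry events",
    remaining_entries = nrow(entries),
    remaining_subjects = n_distinct(entries$subject_id)
  ))

  for (i in seq_along(defn$inclusion_rules)) {
    r <- defn$inclusion_rules[[i]]
    if (nrow(entries) > 0) {
      ev <- matching_events(store, defn, r$domain, r$concept_set_id) %>%
        select("person_id", "event_date")
      counts <- entries %>%
        left_join(ev, by = c(subject_id = "person_id"),
                  relationship = "many-to-many") %>%
        mutate(offset = as.numeric(.data$event_date) - as.numeric(.data$cohort_start_date),
               hit = !is.na(.data$event_date) &
                 .data$offset >= r$window[1] & .data$offset <= r$window[2]) %>%
        group_by(.data$subject_id, .data$cohort_start_date) %>%
        summarise(n_hits = sum(.data$hit), .groups = "drop")
      entries <- entries %>%
        left_join(counts, by = c("subject_id", "cohort_start_date")) %>%
        mutate(n_hits = dplyr::coalesce(.data$n_hits, 0L)) %>%
        filter(switch(r$occurrence_count$comparator,
                      at_least = .data$n_hits >= r$occurrence_count$n,
                      at_most  = .data$n_hits <= r$occurrence_count$n,
                      exactly  = .data$n_hits == r$occurrence_count$n,
                      abort(sprintf("Unknown comparator '%s'", r$occurrence_count$comparator)))) %>%
        select(-"n_hits")
    }
    attrition[[i + 1]] <- tibble(
      cohort_id = defn$cohort_id, rule_sequence = i, rule_name = r$name,
      remaining_entries = nrow(entries),
      remaining_subjects = n_distinct(entries$subject_id)
    )
  }

  cohort_end <- if (identical(defn$exit$strategy, "end_of_observation")) {
    entries$period_end
  } else {
    pmin(entries$cohort_start_date + defn$exit$days, entries$period_end)
  }
  entries <- entries %>%
    mutate(cohort_end_date = cohort_end) %>%
    select("cohort_id", "subject_id", "cohort_start_date", "cohort_end_date") %>%
    arrange(.data$subject_id, .data$cohort_start_date)

  structure(
    list(entries = entries, attrition = bind_rows(attrition),
         cohort_id = defn$cohort_id, name = defn$name),
    class = "cohort_instantiation"
  )
}

#' @export
print.cohort_instantiation <- function(x, ...) {
  cat(sprintf("<cohort_instantiation %d '%s'>: %d entries, %d subjects\n",
              x$cohort_id, x$name, nrow(x$entries), n_distinct(x$entries$subject_id)))
  invisible(x)
}

#' Collapse cohort entries into eras
#'
#' Per subject (within each cohort), entries separated by gaps of at most
#' `gap_days` are merged into one era; the output is non-overlapping and
#' sorted. Useful for externally instantiated cohorts and unions of
#' definitions where a person can enter at multiple distinct temporal periods.
#'
#' @param entries Cohort-entry tibble (`cohort_id`, `subject_id`,
#'   `cohort_start_date`, `cohort_end_date`) or a `cohort_instantiation`.
#' @param gap_days Non-negative integer gap tolerance.
#' @return Collapsed entry tibble.
#' @export
collapse_eras <- function(entries, gap_days = 0L) {
  if (inherits(entries, "cohort_instantiation")) entries <- entries$entries
  if (gap_days < 0) abort("gap_days must be >= 0")
  gap_days <- as.integer(gap_days)
  if (nrow(entries) == 0) return(as_tibble(entries))
  entries %>%
    group_by(.data$cohort_id, .data$subject_id) %>%
    dplyr::reframe({
      m <- merge_day_intervals(.data$cohort_start_date, .data$cohort_end_date, gap_days)
      tibble(cohort_start_date = m$start, cohort_end_date = m$end)
    }) %>%
    as_tibble()
}

#' Union of instantiated cohorts
#'
#' Combines the entries of several instantiations of disjunctive entry arms
#' into one cohort id: entries are pooled, deduplicated on subject and start
#' date (earliest start wins per subject-date after era collapse with gap 0).
#'
#' @param ... `cohort_instantiation` objects or entry tibbles.
#' @param cohort_id Cohort id assigned to the union.
#' @return Entry tibble of the unioned cohort (era-collapsed, gap 0).
#' @export
union_cohorts <- function(..., cohort_id) {
  parts <- purrr::map(list(...), function(x) {
    if (inherits(x, "cohort_instantiation")) x$entries else as_tibble(x)
  })
  new_id <- as.integer(cohort_id)
  pooled <- bind_rows(parts) %>%
    mutate(cohort_id = new_id) %>%
    distinct(.data$cohort_id, .data$subject_id, .data$cohort_start_date,
             .keep_all = TRUE)
  collapse_eras(pooled, gap_days = 0L)
}

#' Read / write instantiated cohorts as 4-column CSV
#'
#' The interchange format for externally instantiated cohorts:
#' `cohort_id, subject_id, cohort_start_date, cohort_end_date`, ISO-8601 dates.
#'
#' @param path CSV file path.
#' @return `read_cohort_csv`: entry tibble. `write_cohort_csv`: `path`,
#'   invisibly.
#' @export
read_cohort_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    cohort_id = readr::col_integer(),
                    subject_id = readr::col_integer(),
                    cohort_start_date = readr::col_date(),
                    cohort_end_date = readr::col_date()
                  ))
}

#' @param entries Entry tibble or `cohort_instantiation`.
#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(entries, path) {
  if (inherits(entries, "cohort_instantiation")) entries <- entries$entries
  readr::write_csv(entries, path)
  invisible(path)
}
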