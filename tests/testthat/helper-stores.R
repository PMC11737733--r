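# Small store builders used across the tests. Fixtures are built in code.

flat_vocab <- function(ids) {
  list(
    concepts = tibble::tibble(
      concept_id = as.integer(ids),
      concept_name = paste0("concept ", ids),
      domain_id = "condition", vocabulary_id = "TEST"
    ),
    ancestors = phenodiag::ancestor_closure(
      tibble::tibble(parent_id = integer(), child_id = integer()), ids
    )
  )
}

# A toy store over an explicit event table; flat vocabulary by default.
toy_store <- function(persons, periods, events = NULL, visits = NULL,
                      vocab = NULL, source_name = "toy") {
  if (is.null(vocab)) {
    ids <- if (is.null(events) || nrow(events) == 0) 1L else unique(events$concept_id)
    vocab <- flat_vocab(ids)
  }
  phenodiag::cdm_store(
    persons = persons, observation_periods = periods,
    clinical_events = events, visits = visits,
    concepts = vocab$concepts, concept_ancestors = vocab$ancestors,
    source_name = source_name
  )
}

# Randomized small store + cohort entries for incidence oracle equivalence:
# multi-period persons, some missing birth years, entries occasionally
# outside observation.
random_store_with_cohort <- function(seed, max_persons = 40L, max_years = 8L) {
  set.seed(seed)
  n <- sample(5:max_persons, 1)
  years <- sample(2:max_years, 1)
  base <- as.Date("2008-01-01")
  span <- years * 365L
  persons <- tibble::tibble(
    person_id = seq_len(n),
    sex = sample(c("FEMALE", "MALE"), n, replace = TRUE),
    year_of_birth = ifelse(stats::runif(n) < 0.1, NA_integer_,
                           sample(1940:2005, n, replace = TRUE))
  )
  periods <- purrr::map_dfr(seq_len(n), function(pid) {
    k <- sample(1:2, 1)
    starts <- base + sample.int(span, k) - 1L
    tibble::tibble(
      person_id = pid, start_date = starts,
      end_date = pmin(starts + sample(30:1200, k, replace = TRUE), base + span)
    )
  })
  entrants <- which(stats::runif(n) < 0.6)
  entries <- purrr::map_dfr(entrants, function(pid) {
    k <- sample(1:2, 1)
    d <- base + sample.int(span, k) - 1L
    tibble::tibble(cohort_id = 1L, subject_id = pid,
                   cohort_start_date = d, cohort_end_date = d + sample(0:200, k, replace = TRUE))
  })
  list(
    store = toy_store(persons, periods),
    entries = if (nrow(entries) > 0) entries else
      tibble::tibble(cohort_id = integer(), subject_id = integer(),
                     cohort_start_date = as.Date(character()),
                     cohort_end_date = as.Date(character()))
  )
}
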