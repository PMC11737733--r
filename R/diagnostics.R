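# Population-level diagnostics computed from a CDM store plus one or more
# instantiated cohorts: counts, stratified incidence rates, time
# distributions, index-event breakdown, visit context, overlap,
# characterization and covariate balance.

as_entries <- function(entries) {
  if (inherits(entries, "cohort_instantiation")) entries <- entries$entries
  as_tibble(entries)
}

pd_result <- function(x, subclass) {
  class(x) <- c(subclass, class(x))
  x
}

first_entry_per_subject <- function(entries) {
  if (nrow(entries) == 0) {
    return(tibble(subject_id = integer(), first_date = as.Date(character())))
  }
  entries %>%
    group_by(.data$subject_id) %>%
    summarise(first_date = min(.data$cohort_start_date), .groups = "drop")
}

#' Cohort entry and subject counts
#'
#' @param entries Cohort-entry tibble or `cohort_instantiation`. A ratio of
#'   entry to subject count above 1 indicates persons entering the cohort at
#'   multiple distinct temporal periods.
#' @return Tibble `cohort_id`, `entry_count`, `subject_count` (one row per
#'   cohort present; zero rows for an empty input).
#' @export
cohort_counts <- function(entries) {
  known_id <- if (inherits(entries, "cohort_instantiation")) entries$cohort_id else NULL
  entries <- as_entries(entries)
  if (nrow(entries) == 0 && !is.null(known_id)) {
    return(pd_result(tibble(cohort_id = known_id, entry_count = 0L,
                            subject_count = 0L), "pd_cohort_count"))
  }
  out <- entries %>%
    group_by(.data$cohort_id) %>%
    summarise(entry_count = dplyr::n(),
              subject_count = n_distinct(.data$subject_id),
              .groups = "drop")
  pd_result(out, "pd_cohort_count")
}

# ---------------------------------------------------------------------------
# Person-time machinery (shared by incidence_rates and truth_incidence).
#
# Conventions (documented in the methods vignette):
#  * observation slices are counted in inclusive days (end - start + 1);
#  * person-years = days / 365.25;
#  * a person's at-risk time is right-censored at their first cohort entry,
#    the entry day itself counting as at risk;
#  * each observation period is left-trimmed by `washout_days` after its
#    start;
#  * slices are split at calendar-year boundaries; age = calendar_year -
#    year_of_birth, banded into 10-year groups.

person_time_slices <- function(store, first_entry = NULL, washout_days = 0L) {
  periods <- store$observation_periods %>%
    left_join(store$persons, by = "person_id")
  if (!is.null(first_entry)) {
    periods <- periods %>%
      left_join(first_entry, by = c(person_id = "subject_id"))
  } else {
    periods$first_date <- as.Date(NA)
  }
  at_start <- periods$start_date + washout_days
  at_end <- pmin(periods$end_date, periods$first_date, na.rm = TRUE)
  keep <- at_end >= at_start
  periods <- periods[keep, , drop = FALSE]
  at_start <- at_start[keep]
  at_end <- at_end[keep]
  if (nrow(periods) == 0) {
    return(tibble(person_id = integer(), sex = character(),
                  year_of_birth = integer(), calendar_year = integer(),
                  age_group = character(), days = integer()))
  }
  y1 <- as.integer(format(at_start, "%Y"))
  y2 <- as.integer(format(at_end, "%Y"))
  idx <- rep(seq_along(y1), y2 - y1 + 1L)
  year <- unlist(purrr::map2(y1, y2, seq))
  slice_start <- pmax(at_start[idx], as.Date(paste0(year, "-01-01")))
  slice_end <- pmin(at_end[idx], as.Date(paste0(year, "-12-31")))
  tibble(
    person_id = periods$person_id[idx],
    sex = periods$sex[idx],
    year_of_birth = periods$year_of_birth[idx],
    calendar_year = year,
    age_group = age_band_label(year - periods$year_of_birth[idx]),
    days = inclusive_days(slice_start, slice_end)
  )
}

# First-ever entry per subject, flagged as a qualifying case when it falls
# inside the at-risk portion of an observation period.
incident_cases <- function(store, entries, washout_days = 0L) {
  first <- first_entry_per_subject(entries)
  if (nrow(first) == 0) {
    return(tibble(subject_id = integer(), first_date = as.Date(character()),
                  sex = character(), calendar_year = integer(),
                  age_group = character()))
  }
  qualifying <- first %>%
    left_join(store$observation_periods, by = c(subject_id = "person_id"),
              relationship = "many-to-many") %>%
    mutate(ok = !is.na(.data$start_date) &
             .data$first_date >= .data$start_date + washout_days &
             .data$first_date <= .data$end_date) %>%
    group_by(.data$subject_id, .data$first_date) %>%
    summarise(ok = any(.data$ok), .groups = "drop") %>%
    filter(.data$ok)
  qualifying %>%
    left_join(store$persons, by = c(subject_id = "person_id")) %>%
    mutate(calendar_year = as.integer(format(.data$first_date, "%Y")),
           age_group = age_band_label(.data$calendar_year - .data$year_of_birth)) %>%
    select("subject_id", "first_date", "sex", "calendar_year", "age_group")
}

#' Stratified incidence rates with person-time denominators
#'
#' Cases are first-ever cohort entries; the denominator population is every
#' person with any observation time in the store, each person's at-risk time
#' right-censored at their first cohort entry (the entry day counts) and
#' left-trimmed by `washout_days` after each observation period start.
#' Person-time is split at calendar-year boundaries; age is banded into
#' 10-year groups from `calendar_year - year_of_birth`. Rates are per 1000
#' person-years (365.25-day years). Rows are emitted for every combination
#' of the requested strata dimensions, including marginal rows where a
#' dimension is absent (`NA`); strata with zero person-time are omitted.
#' Persons lacking `year_of_birth` are excluded from age-stratified rows but
#' retained in all others.
#'
#' @param entries Cohort-entry tibble or `cohort_instantiation`
#'   (era-collapsed).
#' @param store A [cdm_store].
#' @param by_age,by_sex,by_year Strata dimensions to include.
#' @param washout_days Days after each observation period start excluded from
#'   at-risk time (and required before a qualifying first entry).
#' @return Tibble `cohort_id`, `age_group`, `sex`, `calendar_year`, `cases`,
#'   `person_years`, `rate_per_1000`.
#' @export
incidence_rates <- function(entries, store, by_age = FALSE, by_sex = FALSE,
                            by_year = FALSE, washout_days = 0L) {
  stopifnot(inherits(store, "cdm_store"))
  entries <- as_entries(entries)
  cid <- if (nrow(entries) > 0) entries$cohort_id[1] else NA_integer_
  if (by_age && all(is.na(store$persons$year_of_birth))) {
    abort("Age stratification requested but no person has year_of_birth.")
  }
  first <- first_entry_per_subject(entries)
  slices <- person_time_slices(store, first, washout_days)
  cases <- incident_cases(store, entries, washout_days)

  dims <- c("age_group", "sex", "calendar_year")[c(by_age, by_sex, by_year)]
  combos <- purrr::map(0:length(dims), ~ utils::combn(dims, .x, simplify = FALSE)) %>%
    purrr::flatten()

  rows <- purrr::map_dfr(combos, function(by) {
    s <- slices
    k <- cases
    if ("age_group" %in% by) {
      s <- filter(s, !is.na(.data$age_group))
      k <- filter(k, !is.na(.data$age_group))
    }
    py <- s %>%
      group_by(across(all_of(by))) %>%
      summarise(person_years = sum(.data$days) / DAYS_PER_YEAR, .groups = "drop")
    cs <- k %>%
      group_by(across(all_of(by))) %>%
      summarise(cases = dplyr::n(), .groups = "drop")
    out <- if (length(by) == 0) {
      mutate(py, cases = if (nrow(cs) > 0) cs$cases[1] else 0L)
    } else {
      py %>%
        left_join(cs, by = by) %>%
        mutate(cases = dplyr::coalesce(.data$cases, 0L))
    }
    for (d in setdiff(c("age_group", "sex", "calendar_year"), by)) {
      out[[d]] <- if (d == "calendar_year") NA_integer_ else NA_character_
    }
    out
  })

  rows <- rows %>%
    filter(.data$person_years > 0) %>%
    mutate(cohort_id = cid,
           rate_per_1000 = .data$cases / .data$person_years * 1000) %>%
    select("cohort_id", "age_group", "sex", "calendar_year",
           "cases", "person_years", "rate_per_1000") %>%
    arrange(.data$age_group, .data$sex, .data$calendar_year)
  pd_result(rows, "pd_incidence")
}

#' Time distributions around cohort entry
#'
#' Per cohort entry, three durations in days: observation start to index,
#' index to cohort end, and index to the end of continuous observation.
#' Entries falling outside any observation period are excluded with a logged
#' count.
#'
#' @param entries Cohort-entry tibble or `cohort_instantiation`.
#' @param store A [cdm_store].
#' @return Tibble with one row per cohort and measure: `cohort_id`,
#'   `measure`, `n`, `mean`, `sd`, `min`, `p10`, `p25`, `median`, `p75`,
#'   `p90`, `max`.
#' @export
time_distributions <- function(entries, store) {
  entries <- as_entries(entries)
  if (nrow(entries) == 0) {
    return(pd_result(tibble(
      cohort_id = integer(), measure = character(), n = integer(),
      mean = double(), sd = double(), min = double(), p10 = double(),
      p25 = double(), median = double(), p75 = double(), p90 = double(),
      max = double()
    ), "pd_time_distribution"))
  }
  joined <- entries %>%
    left_join(store$observation_periods, by = c(subject_id = "person_id"),
              relationship = "many-to-many") %>%
    filter(!is.na(.data$start_date),
           .data$cohort_start_date >= .data$start_date,
           .data$cohort_start_date <= .data$end_date)
  n_excluded <- nrow(entries) - nrow(distinct(joined, .data$cohort_id,
                                              .data$subject_id, .data$cohort_start_date))
  if (n_excluded > 0) {
    inform(sprintf("time_distributions: %d entr%s outside any observation period excluded.",
                   n_excluded, if (n_excluded == 1) "y" else "ies"))
  }
  if (nrow(joined) == 0) {
    return(time_distributions(entries[0, ], store))
  }
  long <- joined %>%
    mutate(
      obs_start_to_index = as.integer(.data$cohort_start_date) - as.integer(.data$start_date),
      index_to_cohort_end = as.integer(.data$cohort_end_date) - as.integer(.data$cohort_start_date),
      index_to_obs_end = as.integer(.data$end_date) - as.integer(.data$cohort_start_date)
    ) %>%
    tidyr::pivot_longer(c("obs_start_to_index", "index_to_cohort_end", "index_to_obs_end"),
                        names_to = "measure", values_to = "days")
  out <- long %>%
    group_by(.data$cohort_id, .data$measure) %>%
    summarise(
      n = dplyr::n(),
      mean = mean(.data$days),
      sd = if (dplyr::n() > 1) stats::sd(.data$days) else 0,
      min = as.double(min(.data$days)),
      p10 = unname(quantile(.data$days, 0.10)),
      p25 = unname(quantile(.data$days, 0.25)),
      median = unname(median(.data$days)),
      p75 = unname(quantile(.data$days, 0.75)),
      p90 = unname(quantile(.data$days, 0.90)),
      max = as.double(max(.data$days)),
      .groups = "drop"
    ) %>%
    mutate(measure = factor(.data$measure,
                            levels = c("obs_start_to_index", "index_to_cohort_end",
                                       "index_to_obs_end"))) %>%
    arrange(.data$cohort_id, .data$measure) %>%
    mutate(measure = as.character(.data$measure))
  pd_result(out, "pd_time_distribution")
}

#' Index event breakdown
#'
#' For every concept in the resolved union of the definition's entry-event
#' concept sets, counts the cohort entries having at least one event of that
#' concept dated exactly on the cohort start date — the codes that likely
#' triggered cohort entry. An entry with k distinct coinciding concepts
#' contributes to k rows; zero-count concepts are omitted.
#'
#' @param entries Cohort-entry tibble or `cohort_instantiation`.
#' @param defn The [cohort_definition] the entries were instantiated from.
#' @param store A [cdm_store].
#' @return Tibble `cohort_id`, `concept_id`, `concept_name`, `entry_count`,
#'   `subject_count`.
#' @export
index_event_breakdown <- function(entries, defn, store) {
  entries <- as_entries(entries)
  entry_concepts <- purrr::map_dfr(defn$entry_events, function(ee) {
    tibble(domain = ee$domain,
           concept_id = resolve_concept_set(
             defn$concept_sets[[as.character(ee$concept_set_id)]], store))
  }) %>% distinct()
  hits <- entries %>%
    inner_join(store$clinical_events, by = c(subject_id = "person_id"),
               relationship = "many-to-many") %>%
    filter(.data$event_date == .data$cohort_start_date) %>%
    semi_join(entry_concepts, by = c("domain", "concept_id"))
  out <- hits %>%
    distinct(.data$cohort_id, .data$subject_id, .data$cohort_start_date,
             .data$concept_id) %>%
    group_by(.data$cohort_id, .data$concept_id) %>%
    summarise(entry_count = dplyr::n(),
              subject_count = n_distinct(.data$subject_id), .groups = "drop") %>%
    left_join(select(store$concepts, "concept_id", "concept_name"),
              by = "concept_id") %>%
    select("cohort_id", "concept_id", "concept_name", "entry_count", "subject_count") %>%
    arrange(dplyr::desc(.data$entry_count), .data$concept_id)
  pd_result(out, "pd_index_event")
}

#' Visit context around cohort entry
#'
#' Classifies each person's visits relative to each cohort entry:
#' * `before` — the visit concluded within 30 days prior to index
#'   (end in `[index-30, index-1]`);
#' * `during` — the visit began before and extended up to or beyond index
#'   (start < index and end >= index);
#' * `simultaneous` — the visit initiated on the index date;
#' * `after` — the visit commenced within 30 days post index
#'   (start in `[index+1, index+30]`).
#' Precedence simultaneous > during > before > after assigns each
#' (entry, visit) pair at most one context. Counts are distinct subjects per
#' visit category and context.
#'
#' @param entries Cohort-entry tibble or `cohort_instantiation`.
#' @param store A [cdm_store].
#' @return Tibble `cohort_id`, `visit_category`, `context`, `subject_count`.
#' @export
visit_context <- function(entries, store) {
  entries <- as_entries(entries)
  paired <- entries %>%
    inner_join(store$visits, by = c(subject_id = "person_id"),
               relationship = "many-to-many") %>%
    mutate(
      so = as.integer(.data$start_date) - as.integer(.data$cohort_start_date),
      eo = as.integer(.data$end_date) - as.integer(.data$cohort_start_date),
      context = dplyr::case_when(
        so == 0 ~ "simultaneous",
        so < 0 & eo >= 0 ~ "during",
        eo >= -30 & eo <= -1 ~ "before",
        so >= 1 & so <= 30 ~ "after",
        TRUE ~ NA_character_
      )
    ) %>%
    filter(!is.na(.data$context))
  out <- paired %>%
    group_by(.data$cohort_id, .data$visit_category, .data$context) %>%
    summarise(subject_count = n_distinct(.data$subject_id), .groups = "drop") %>%
    mutate(context = factor(.data$context,
                            levels = c("before", "during", "simultaneous", "after"))) %>%
    arrange(.data$cohort_id, .data$visit_category, .data$context) %>%
    mutate(context = as.character(.data$context))
  pd_result(out, "pd_visit_context")
}

#' Subject-level overlap between two cohorts
#'
#' @param entries_a,entries_b Cohort-entry tibbles or `cohort_instantiation`s
#'   from the same store.
#' @return One-row tibble `cohort_id_a`, `cohort_id_b`, `n_both`, `n_only_a`,
#'   `n_only_b`.
#' @export
cohort_overlap <- function(entries_a, entries_b) {
  a <- as_entries(entries_a)
  b <- as_entries(entries_b)
  sa <- unique(a$subject_id)
  sb <- unique(b$subject_id)
  out <- tibble(
    cohort_id_a = if (nrow(a) > 0) a$cohort_id[1] else NA_integer_,
    cohort_id_b = if (nrow(b) > 0) b$cohort_id[1] else NA_integer_,
    n_both = length(intersect(sa, sb)),
    n_only_a = length(setdiff(sa, sb)),
    n_only_b = length(setdiff(sb, sa))
  )
  pd_result(out, "pd_overlap")
}

DEFAULT_CHARACTERIZATION_WINDOWS <- list(
  c(-365, -31), c(-30, -1), c(0, 0), c(1, 30), c(31, 365)
)

#' Temporal cohort characterization
#'
#' Prevalence of all observed clinical events at different time periods
#' relative to the index date. Each subject is anchored on their *first*
#' cohort entry; for each window (closed interval in days, day 0 = index) a
#' concept counts a subject when at least one event of that concept falls in
#' the window (per-subject dedup, so duplicated events never change
#' proportions). With `rollup = TRUE` every observed concept is additionally
#' reported once per designated hierarchy group (nearest designated
#' ancestor), with per-subject dedup within the group. Demographic covariates
#' (10-year age band at index, sex) are emitted under the index-date window.
#'
#' @param entries Cohort-entry tibble or `cohort_instantiation`.
#' @param store A [cdm_store].
#' @param windows List of length-2 numeric vectors; defaults to the five
#'   standard windows `(-365,-31), (-30,-1), (0,0), (1,30), (31,365)`.
#' @param rollup Also emit hierarchy-group rows.
#' @param groups Designated group concept ids for roll-up; defaults to the
#'   synthetic vocabulary's groups.
#' @return Tibble `cohort_id`, `window_start`, `window_end`,
#'   `covariate_type` (`demographic`/`event`/`event_group`), `concept_id`,
#'   `covariate_name`, `n_subjects`, `proportion`.
#' @export
characterize <- function(entries, store,
                         windows = DEFAULT_CHARACTERIZATION_WINDOWS,
                         rollup = FALSE, groups = synthetic_rollup_groups()) {
  entries <- as_entries(entries)
  empty <- tibble(
    cohort_id = integer(), window_start = double(), window_end = double(),
    covariate_type = character(), concept_id = integer(),
    covariate_name = character(), n_subjects = integer(), proportion = double()
  )
  if (nrow(entries) == 0) return(pd_result(empty, "pd_characterization"))

  anchors <- entries %>%
    group_by(.data$cohort_id, .data$subject_id) %>%
    summarise(index_date = min(.data$cohort_start_date), .groups = "drop")
  n_cohort <- anchors %>% count(.data$cohort_id, name = "n_total")

  ev <- anchors %>%
    inner_join(store$clinical_events, by = c(subject_id = "person_id"),
               relationship = "many-to-many") %>%
    mutate(offset = as.integer(.data$event_date) - as.integer(.data$index_date))

  grp_map <- if (rollup) {
    rollup_concepts(unique(ev$concept_id), store$concept_ancestors, groups) %>%
      filter(.data$group_concept_id != .data$concept_id)
  } else {
    NULL
  }

  concept_names <- setNames(store$concepts$concept_name,
                            as.character(store$concepts$concept_id))
  name_of <- function(id) {
    nm <- unname(concept_names[as.character(id)])
    as.character(ifelse(is.na(nm), paste0("concept ", id), nm))
  }

  windows <- purrr::map(windows, as.numeric)
  win_rows <- purrr::map_dfr(windows, function(w) {
    in_win <- ev %>%
      filter(.data$offset >= w[1], .data$offset <= w[2])
    raw <- in_win %>%
      distinct(.data$cohort_id, .data$subject_id, .data$concept_id) %>%
      group_by(.data$cohort_id, .data$concept_id) %>%
      summarise(n_subjects = dplyr::n(), .groups = "drop") %>%
      mutate(covariate_type = "event",
             covariate_name = name_of(.data$concept_id))
    out <- raw
    if (!is.null(grp_map) && nrow(grp_map) > 0) {
      grouped <- in_win %>%
        inner_join(grp_map, by = "concept_id") %>%
        distinct(.data$cohort_id, .data$subject_id, .data$group_concept_id) %>%
        group_by(.data$cohort_id, concept_id = .data$group_concept_id) %>%
        summarise(n_subjects = dplyr::n(), .groups = "drop") %>%
        mutate(covariate_type = "event_group",
               covariate_name = name_of(.data$concept_id))
      out <- bind_rows(out, grouped)
    }
    out %>% mutate(window_start = w[1], window_end = w[2])
  })

  demo <- anchors %>%
    left_join(store$persons, by = c(subject_id = "person_id")) %>%
    mutate(
      age_group = age_band_label(
        as.integer(format(.data$index_date, "%Y")) - .data$year_of_birth)
    ) %>%
    tidyr::pivot_longer(c("age_group", "sex"), names_to = "dim", values_to = "value") %>%
    filter(!is.na(.data$value)) %>%
    group_by(.data$cohort_id, .data$dim, .data$value) %>%
    summarise(n_subjects = dplyr::n(), .groups = "drop") %>%
    mutate(covariate_type = "demographic",
           concept_id = NA_integer_,
           covariate_name = paste0(.data$dim, ": ", .data$value),
           window_start = 0, window_end = 0) %>%
    select(-"dim", -"value")

  out <- bind_rows(win_rows, demo) %>%
    left_join(n_cohort, by = "cohort_id") %>%
    mutate(proportion = .data$n_subjects / .data$n_total) %>%
    select("cohort_id", "window_start", "window_end", "covariate_type",
           "concept_id", "covariate_name", "n_subjects", "proportion") %>%
    arrange(.data$cohort_id, .data$window_start, .data$window_end,
            .data$covariate_type, .data$concept_id, .data$covariate_name)
  out <- pd_result(out, "pd_characterization")
  attr(out, "pd_windows") <- windows
  out
}

#' Covariate balance between two characterized cohorts
#'
#' Pairwise comparison of characterization output: for each covariate and
#' window, the two prevalences and the signed standardized (mean) difference
#' for a binary covariate,
#' \deqn{SMD = (p_t - p_c) / \sqrt{(p_t(1-p_t) + p_c(1-p_c))/2}.}
#' Covariates absent from one side are treated as proportion 0 there. The
#' SMD is emitted as `NA` when both proportions are 0 or both are 1 (the
#' pooled standard deviation vanishes with no contrast to standardize).
#'
#' @param rows_target,rows_comparator Output of [characterize()], computed
#'   with identical windows and roll-up policy.
#' @return Tibble `cohort_id_target`, `cohort_id_comparator`,
#'   `window_start`, `window_end`, `covariate_type`, `concept_id`,
#'   `covariate_name`, `p_target`, `p_comparator`, `smd`.
#' @export
compare_characterizations <- function(rows_target, rows_comparator) {
  wt <- attr(rows_target, "pd_windows")
  wc <- attr(rows_comparator, "pd_windows")
  if (!is.null(wt) && !is.null(wc) && !identical(wt, wc)) {
    abort("compare_characterizations: the two row sets use different window sets.")
  }
  key <- c("window_start", "window_end", "covariate_type", "concept_id", "covariate_name")
  t <- as_tibble(rows_target) %>% select(all_of(key), p_target = "proportion",
                                         cohort_id_target = "cohort_id")
  c_ <- as_tibble(rows_comparator) %>% select(all_of(key), p_comparator = "proportion",
                                              cohort_id_comparator = "cohort_id")
  cid_t <- if (nrow(t) > 0) t$cohort_id_target[1] else NA_integer_
  cid_c <- if (nrow(c_) > 0) c_$cohort_id_comparator[1] else NA_integer_
  out <- dplyr::full_join(select(t, -"cohort_id_target"),
                          select(c_, -"cohort_id_comparator"), by = key) %>%
    mutate(
      p_target = dplyr::coalesce(.data$p_target, 0),
      p_comparator = dplyr::coalesce(.data$p_comparator, 0),
      smd = binary_smd(.data$p_target, .data$p_comparator),
      cohort_id_target = cid_t,
      cohort_id_comparator = cid_c
    ) %>%
    select("cohort_id_target", "cohort_id_comparator", all_of(key),
           "p_target", "p_comparator", "smd") %>%
    arrange(.data$window_start, .data$window_end, .data$covariate_type,
            .data$concept_id, .data$covariate_name)
  pd_result(out, "pd_balance")
}

#' Standardized difference of two binary prevalences
#'
#' @param p_target,p_comparator Proportions in `[0, 1]` (vectorized).
#' @return Signed SMD; `NA` where the pooled standard deviation is zero and
#'   the proportions are equal; `+/-Inf` where it is zero and they differ.
#' @export
binary_smd <- function(p_target, p_comparator) {
  denom <- sqrt((p_target * (1 - p_target) + p_comparator * (1 - p_comparator)) / 2)
  num <- p_target - p_comparator
  ifelse(denom == 0,
         ifelse(num == 0, NA_real_, sign(num) * Inf),
         num / denom)
}

#' Relative difference between a simple and a restrictive cohort count
#'
#' `(1 - count_restrictive / count_simple) * 100`, rounded half-up to one
#' decimal — the percentage reduction a more restrictive phenotype algorithm
#' causes relative to a simpler one for the same condition.
#'
#' @param count_simple Positive count from the simpler algorithm.
#' @param count_restrictive Count from the restrictive algorithm.
#' @return Percentage (one decimal), vectorized.
#' @export
relative_difference <- function(count_simple, count_restrictive) {
  if (any(count_simple <= 0)) {
    abort("relative_difference undefined: count_simple must be > 0")
  }
  round_half_up((1 - count_restrictive / count_simple) * 100, 1L)
}
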