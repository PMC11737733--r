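# Synthetic OMOP-shaped data sources with controllable demographics,
# disease-onset rate, coding lag, treatment/symptom emission and visit
# patterns, carrying ground truth so diagnostics can be checked against the
# generating process.

#' Scenario configuration for the synthetic-data generator
#'
#' @param n_persons Number of persons.
#' @param calendar_span `c(start_year, end_year)` of the simulated source
#'   (span of at least 1 year).
#' @param sex_ratio Proportion of females.
#' @param age_distribution Weights over the ten 10-year age bands
#'   (age at the start of the span, bands 0-9 ... 90-99).
#' @param onset_rate_per_1000py Disease onset rate per 1000 person-years of
#'   observed time (exponential waiting-time process).
#' @param sex_multiplier Named multipliers (`FEMALE`, `MALE`) applied to the
#'   onset hazard.
#' @param age_multiplier Optional numeric vector of length 10 (per band)
#'   multiplying the onset hazard; default flat.
#' @param coding_lag Distribution of the delay, in days, from true onset to
#'   the first diagnosis code: `list(type = "constant", days = )` or
#'   `list(type = "geometric", mean = )`.
#' @param p_treatment_before_code Probability that a treatment code precedes
#'   the diagnosis code (emitted at true onset); otherwise treatment follows
#'   the coded diagnosis within 30 days. Injects index-date misclassification:
#'   patients receive treatment before their diagnosis is coded.
#' @param symptom_emission `list(prob = , window_days = )`: each symptom
#'   concept is emitted with `prob`, dated up to `window_days` before onset.
#' @param p_repeat_diagnosis Probability that a coded diagnosis is followed
#'   by a confirmatory repeat diagnosis code 30-365 days later (emitted only
#'   while observed).
#' @param background_code_rate Noise events per person-year of observation.
#' @param visit_model Named probabilities (`outpatient`, `inpatient`,
#'   `emergency`, `none`) that an emitted event is attached to a visit of
#'   that category.
#' @param diagnosis_concepts,treatment_concepts,symptom_concepts Concept ids
#'   (from the synthetic vocabulary) used for disease codes.
#' @param source_name Label of the generated source.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return A validated `scenario_config`.
#' @export
scenario_config <- function(n_persons = 1000L,
                            calendar_span = c(2010L, 2019L),
                            sex_ratio = 0.5,
                            age_distribution = c(6, 6, 7, 7, 7, 6, 5, 3, 2, 1),
                            onset_rate_per_1000py = 1.0,
                            sex_multiplier = c(FEMALE = 1, MALE = 1),
                            age_multiplier = NULL,
                            coding_lag = list(type = "constant", days = 0L),
                            p_treatment_before_code = 0,
                            symptom_emission = list(prob = 0.3, window_days = 60L),
                            p_repeat_diagnosis = 0.5,
                            background_code_rate = 2.0,
                            visit_model = c(outpatient = 0.75, inpatient = 0.05,
                                            emergency = 0.05, none = 0.15),
                            diagnosis_concepts = c(1101L, 1102L, 1103L, 1105L),
                            treatment_concepts = c(4101L, 4201L, 4301L),
                            symptom_concepts = c(1201L, 1211L),
                            source_name = "synthetic",
                            seed = 1L) {
  problems <- character()
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(n_persons >= 1, "n_persons must be >= 1")
  chk(length(calendar_span) == 2 && calendar_span[2] >= calendar_span[1],
      "calendar_span must be (start_year, end_year) with span >= 1 year")
  chk(sex_ratio >= 0 && sex_ratio <= 1, "sex_ratio must be in [0, 1]")
  chk(length(age_distribution) == 10 && all(age_distribution >= 0) &&
        sum(age_distribution) > 0, "age_distribution needs 10 non-negative weights")
  chk(onset_rate_per_1000py >= 0, "onset_rate_per_1000py must be >= 0")
  chk(p_treatment_before_code >= 0 && p_treatment_before_code <= 1,
      "p_treatment_before_code must be in [0, 1]")
  chk(symptom_emission$prob >= 0 && symptom_emission$prob <= 1,
      "symptom_emission$prob must be in [0, 1]")
  chk(p_repeat_diagnosis >= 0 && p_repeat_diagnosis <= 1,
      "p_repeat_diagnosis must be in [0, 1]")
  chk(background_code_rate >= 0, "background_code_rate must be >= 0")
  chk(abs(sum(visit_model) - 1) < 1e-8, "visit_model probabilities must sum to 1")
  chk(coding_lag$type %in% c("constant", "geometric"),
      "coding_lag$type must be 'constant' or 'geometric'")
  if (length(problems) > 0) {
    abort(paste0("Invalid scenario configuration:\n",
                 paste("-", problems, collapse = "\n")))
  }
  if (is.null(age_multiplier)) age_multiplier <- rep(1, 10)
  structure(
    list(
      n_persons = as.integer(n_persons), calendar_span = as.integer(calendar_span),
      sex_ratio = sex_ratio, age_distribution = age_distribution,
      onset_rate_per_1000py = onset_rate_per_1000py,
      sex_multiplier = sex_multiplier, age_multiplier = age_multiplier,
      coding_lag = coding_lag,
      p_treatment_before_code = p_treatment_before_code,
      symptom_emission = symptom_emission,
      p_repeat_diagnosis = p_repeat_diagnosis,
      background_code_rate = background_code_rate,
      visit_model = visit_model,
      diagnosis_concepts = as.integer(diagnosis_concepts),
      treatment_concepts = as.integer(treatment_concepts),
      symptom_concepts = as.integer(symptom_concepts),
      source_name = source_name, seed = as.integer(seed)
    ),
    class = "scenario_config"
  )
}

#' Shipped scenario presets
#'
#' `"sle_like"`: female-skewed onset in younger adults with a substantial
#' treatment-before-code mass and a long coding lag, emulating index-date
#' misclassification where treatment precedes the coded diagnosis.
#' `"ad_like"`: elderly onset with dementia codes and anti-dementia drugs,
#' suited to comparing a simple against a restrictive definition.
#'
#' @param preset `"sle_like"` or `"ad_like"`.
#' @param ... Overrides passed to [scenario_config()].
#' @return A `scenario_config`.
#' @export
scenario_preset <- function(preset = c("sle_like", "ad_like"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    sle_like = list(
      sex_ratio = 0.5,
      sex_multiplier = c(FEMALE = 5 / 3, MALE = 1 / 3),
      age_distribution = c(4, 8, 10, 10, 8, 5, 3, 1.5, 0.4, 0.1),
      onset_rate_per_1000py = 1.0,
      coding_lag = list(type = "geometric", mean = 60),
      p_treatment_before_code = 0.4,
      symptom_emission = list(prob = 0.5, window_days = 90L),
      p_repeat_diagnosis = 0.4,
      diagnosis_concepts = c(1101L, 1102L, 1103L, 1105L),
      treatment_concepts = c(4101L, 4201L, 4301L),
      symptom_concepts = c(1201L, 1211L),
      source_name = "sle_like"
    ),
    ad_like = list(
      sex_ratio = 0.55,
      sex_multiplier = c(FEMALE = 1.1, MALE = 0.9),
      age_distribution = c(0, 0, 0, 0, 1, 2, 6, 10, 8, 3),
      onset_rate_per_1000py = 5.0,
      coding_lag = list(type = "geometric", mean = 30),
      p_treatment_before_code = 0.2,
      symptom_emission = list(prob = 0.6, window_days = 180L),
      p_repeat_diagnosis = 0.6,
      diagnosis_concepts = c(2101L, 2102L),
      treatment_concepts = c(4511L, 4521L),
      symptom_concepts = c(2451L, 2452L),
      source_name = "ad_like"
    )
  )
  do.call(scenario_config, utils::modifyList(base, list(...)))
}

# sample() with the 1:x surprise removed (concept pools may be length 1)
sample_vec <- function(x, k) x[sample.int(length(x), k, replace = TRUE)]

draw_lag <- function(n, coding_lag) {
  switch(coding_lag$type,
         constant = rep(as.integer(coding_lag$days), n),
         geometric = rgeom(n, prob = 1 / (coding_lag$mean + 1)))
}

#' Generate a synthetic OMOP-shaped source with ground truth
#'
#' Persons are drawn per the configured demographics; each gets one
#' observation period inside the calendar span (random in/out dates, at least
#' about a year where the span allows). Disease onsets follow an exponential
#' waiting-time process at the configured hazard within observed time;
#' diagnosis codes are emitted at onset + coding lag, treatment codes before
#' the diagnosis code with probability `p_treatment_before_code` (at true
#' onset) and otherwise shortly after it, symptoms before onset, plus
#' background noise events; every emitted event may be attached to a visit.
#' All draws consume a single pseudo-random stream keyed by `seed`, in the
#' order: demographics, observation periods, onsets, coding lags, treatment,
#' symptoms, noise, visits.
#'
#' @param config A [scenario_config()].
#' @return List with `store` (a validated [cdm_store] over the synthetic
#'   vocabulary) and `truth` (`persons`: per-person true onset dates;
#'   `events`: per-event provenance tags `diagnosis`/`treatment`/`symptom`/
#'   `noise`, aligned with the store's `event_id`).
#' @export
generate_source <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  vocab <- synthetic_vocabulary()
  n <- config$n_persons
  span_start <- as.Date(sprintf("%d-01-01", config$calendar_span[1]))
  span_end <- as.Date(sprintf("%d-12-31", config$calendar_span[2]))
  span_days <- inclusive_days(span_start, span_end)

  # Demographics.
  sex <- ifelse(runif(n) < config$sex_ratio, "FEMALE", "MALE")
  band <- sample.int(10, n, replace = TRUE, prob = config$age_distribution) - 1L
  age_at_start <- band * 10L + sample.int(10, n, replace = TRUE) - 1L
  yob <- config$calendar_span[1] - age_at_start
  persons <- tibble(person_id = seq_len(n), sex = sex, year_of_birth = yob)

  # Observation periods: random entry in the first 30% of the span, exit
  # uniform between ~1 year later and the span end.
  start_off <- floor(runif(n, 0, max(1, span_days * 0.3)))
  obs_start <- span_start + start_off
  min_end <- pmin(obs_start + 364L, span_end)
  obs_end <- min_end + floor(runif(n) * (as.numeric(span_end - min_end) + 1))
  periods <- tibble(person_id = seq_len(n), start_date = obs_start,
                    end_date = obs_end)

  # Onsets: exponential waiting time within observed days.
  hazard_day <- config$onset_rate_per_1000py / 1000 / DAYS_PER_YEAR *
    unname(config$sex_multiplier[sex]) * config$age_multiplier[band + 1L]
  wait <- rep(Inf, n)
  pos <- hazard_day > 0
  wait[pos] <- rexp(sum(pos), rate = hazard_day[pos])
  onset <- obs_start + floor(wait)
  has_onset <- is.finite(wait) & onset <= obs_end
  onset[!has_onset] <- NA

  onset_ids <- which(has_onset)
  ev_list <- list()
  add_events <- function(person_id, concept_id, domain, date, provenance) {
    ev_list[[length(ev_list) + 1]] <<- tibble(
      person_id = as.integer(person_id), concept_id = as.integer(concept_id),
      domain = domain, event_date = date, end_date = as.Date(NA),
      provenance = provenance
    )
  }

  # Diagnosis codes at onset + coding lag.
  lag <- draw_lag(length(onset_ids), config$coding_lag)
  diag_date <- onset[onset_ids] + lag
  diag_ok <- diag_date <= obs_end[onset_ids]
  if (any(diag_ok)) {
    ids <- onset_ids[diag_ok]
    add_events(ids, sample_vec(config$diagnosis_concepts, length(ids)),
               "condition", diag_date[diag_ok], "diagnosis")
  }

  # Confirmatory repeat diagnosis 30-365 days after the coded one.
  rep_draw <- runif(length(onset_ids)) < config$p_repeat_diagnosis
  rep_date <- diag_date + 30L + floor(runif(length(onset_ids), 0, 336))
  rep_ok <- diag_ok & rep_draw & rep_date <= obs_end[onset_ids]
  if (any(rep_ok)) {
    ids <- onset_ids[rep_ok]
    add_events(ids, sample_vec(config$diagnosis_concepts, length(ids)),
               "condition", rep_date[rep_ok], "diagnosis")
  }

  # Treatment: before the coded diagnosis (at true onset) with probability
  # p_treatment_before_code, else 0-30 days after the coded diagnosis.
  before <- runif(length(onset_ids)) < config$p_treatment_before_code
  trt_date <- as.Date(rep(NA_integer_, length(onset_ids)), origin = "1970-01-01")
  trt_date[before] <- onset[onset_ids][before]
  after_ok <- !before & diag_ok
  trt_date[after_ok] <- diag_date[after_ok] +
    floor(runif(sum(after_ok), 0, 31))
  trt_ok <- !is.na(trt_date) & trt_date <= obs_end[onset_ids]
  if (any(trt_ok)) {
    ids <- onset_ids[trt_ok]
    add_events(ids, sample_vec(config$treatment_concepts, length(ids)),
               "drug", trt_date[trt_ok], "treatment")
  }

  # Symptoms before onset.
  for (sc in config$symptom_concepts) {
    emit <- runif(length(onset_ids)) < config$symptom_emission$prob
    if (!any(emit)) next
    ids <- onset_ids[emit]
    s_date <- onset[ids] - floor(runif(length(ids), 0, config$symptom_emission$window_days + 1))
    s_date <- pmax(s_date, obs_start[ids])
    add_events(ids, sc, "condition", s_date, "symptom")
  }

  # Background noise events across all four event domains.
  obs_years <- inclusive_days(obs_start, obs_end) / DAYS_PER_YEAR
  n_noise <- rpois(n, config$background_code_rate * obs_years)
  if (sum(n_noise) > 0) {
    pid <- rep(seq_len(n), n_noise)
    offs <- floor(runif(sum(n_noise)) * rep(inclusive_days(obs_start, obs_end), n_noise))
    pools <- list(
      condition = 3000L + 1:60, drug = 4900L + 1:40,
      procedure = 5900L + 1:20, measurement = 6900L + 1:20
    )
    dom <- sample(names(pools), sum(n_noise), replace = TRUE,
                  prob = c(0.45, 0.3, 0.15, 0.10))
    cid <- integer(length(dom))
    for (d in names(pools)) {
      idx <- dom == d
      cid[idx] <- sample_vec(pools[[d]], sum(idx))
    }
    add_events(pid, cid, dom, obs_start[pid] + offs, "noise")
  }

  events <- if (length(ev_list) > 0) bind_rows(ev_list) else
    tibble(person_id = integer(), concept_id = integer(), domain = character(),
           event_date = as.Date(character()), end_date = as.Date(character()),
           provenance = character())

  # Visits attached to events.
  visits <- NULL
  if (nrow(events) > 0) {
    cat_draw <- sample(names(config$visit_model), nrow(events), replace = TRUE,
                       prob = config$visit_model)
    with_visit <- cat_draw != "none"
    if (any(with_visit)) {
      los <- ifelse(cat_draw[with_visit] == "inpatient",
                    1L + floor(runif(sum(with_visit), 0, 7)), 0L)
      visits <- tibble(
        person_id = events$person_id[with_visit],
        visit_category = cat_draw[with_visit],
        start_date = events$event_date[with_visit],
        end_date = pmin(events$event_date[with_visit] + los,
                        obs_end[events$person_id[with_visit]])
      )
    }
  }

  store <- cdm_store(
    persons = persons,
    observation_periods = periods,
    clinical_events = select(events, -"provenance"),
    visits = visits,
    concepts = vocab$concepts,
    concept_ancestors = vocab$concept_ancestors,
    source_name = config$source_name
  )
  truth <- structure(
    list(
      persons = tibble(person_id = seq_len(n), onset_date = onset),
      events = tibble(event_id = seq_len(nrow(events)),
                      provenance = events$provenance),
      source_name = config$source_name
    ),
    class = "ground_truth"
  )
  list(store = store, truth = truth)
}

#' Gold-standard incidence from ground truth
#'
#' The true onset rate per 1000 person-years, computed from the generator's
#' onset dates with the same person-time conventions as [incidence_rates()]
#' (inclusive days, 365.25-day years, at-risk time censored at onset with the
#' onset day counting). Because a diagnosis-code phenotype algorithm can only
#' lose cases when coding is lossy, this rate bounds any code-based estimate
#' from above when lags can push codes past the observation end.
#'
#' @param truth The `truth` element of [generate_source()] output.
#' @param store The matching `store` element.
#' @return Scalar rate per 1000 person-years.
#' @export
truth_incidence <- function(truth, store) {
  stopifnot(inherits(truth, "ground_truth"), inherits(store, "cdm_store"))
  if (!identical(truth$source_name, store$source_name)) {
    abort("truth and store come from different generations (source_name mismatch)")
  }
  onsets <- truth$persons %>%
    filter(!is.na(.data$onset_date)) %>%
    select(subject_id = "person_id", first_date = "onset_date")
  slices <- person_time_slices(store, onsets, washout_days = 0L)
  py <- sum(slices$days) / DAYS_PER_YEAR
  if (py == 0) return(0)
  entries <- onsets %>%
    rename(cohort_start_date = "first_date") %>%
    mutate(cohort_id = 0L, cohort_end_date = .data$cohort_start_date)
  cases <- nrow(incident_cases(store, entries, washout_days = 0L))
  cases / py * 1000
}
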