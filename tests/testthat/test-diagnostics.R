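entries_of <- function(...) {
  rows <- list(...)
  purrr::map_dfr(rows, function(r) {
    tibble::tibble(cohort_id = r[[1]], subject_id = r[[2]],
                   cohort_start_date = as.Date(r[[3]]),
                   cohort_end_date = as.Date(r[[4]]))
  })
}

test_that("cohort counts distinguish entries from distinct subjects", {
  e <- entries_of(list(1L, 1L, "2010-01-01", "2010-06-30"),
                  list(1L, 1L, "2011-01-01", "2011-06-30"),
                  list(1L, 2L, "2010-03-01", "2010-12-31"))
  cc <- cohort_counts(e)
  expect_equal(cc$entry_count, 3L)
  expect_equal(cc$subject_count, 2L)
  expect_equal(nrow(cohort_counts(e[0, ])), 0)
  # brute-force distinct count on a random duplication structure
  set.seed(1)
  ids <- sample(1:40, 120, replace = TRUE)
  e2 <- tibble::tibble(cohort_id = 2L, subject_id = ids,
                       cohort_start_date = as.Date("2010-01-01") + seq_along(ids),
                       cohort_end_date = as.Date("2010-01-02") + seq_along(ids))
  expect_equal(cohort_counts(e2)$subject_count, length(unique(ids)))
})

test_that("time distributions reproduce calendar day subtraction", {
  st <- toy_store(
    tibble::tibble(person_id = 1L, sex = "FEMALE", year_of_birth = 1980L),
    tibble::tibble(person_id = 1L, start_date = as.Date("2010-01-01"),
                   end_date = as.Date("2012-12-31"))
  )
  e <- entries_of(list(1L, 1L, "2011-01-01", "2011-06-30"))
  td <- time_distributions(e, st)
  stat <- function(m) td[td$measure == m, ]
  expect_equal(stat("obs_start_to_index")$mean, 365)
  expect_equal(stat("index_to_cohort_end")$mean, 180)
  expect_equal(stat("index_to_obs_end")$mean, 730)
  # single-value sample: all statistics equal the value, sd 0
  r <- stat("obs_start_to_index")
  expect_true(all(unlist(r[c("min", "p10", "p25", "median", "p75", "p90", "max")]) == 365))
  expect_equal(r$sd, 0)
  # entry starting on observation start
  e0 <- entries_of(list(1L, 1L, "2010-01-01", "2010-06-30"))
  expect_equal(time_distributions(e0, st)[1, ]$mean[
    time_distributions(e0, st)$measure[1] == "obs_start_to_index"], 0)
  # entry outside any observation period is excluded with a message
  e_out <- entries_of(list(1L, 1L, "2013-06-01", "2013-12-31"))
  expect_message(out <- time_distributions(e_out, st), "outside")
  expect_equal(nrow(out), 0)
})

test_that("index event breakdown multi-attributes same-day concepts", {
  ev <- tibble::tibble(
    person_id = c(1L, 1L, 1L), concept_id = c(10L, 20L, 30L),
    domain = c("condition", "condition", "condition"),
    event_date = as.Date(c("2011-01-01", "2011-01-01", "2010-12-31")),
    end_date = as.Date(NA)
  )
  st <- toy_store(
    tibble::tibble(person_id = 1L, sex = "FEMALE", year_of_birth = 1980L),
    tibble::tibble(person_id = 1L, start_date = as.Date("2010-01-01"),
                   end_date = as.Date("2012-12-31")),
    ev, vocab = flat_vocab(c(10L, 20L, 30L))
  )
  defn <- cohort_definition(
    cohort_id = 1L, name = "t",
    concept_sets = list(concept_set(1, "s", tibble::tibble(
      concept_id = c(10L, 20L, 30L), include_descendants = FALSE, is_excluded = FALSE))),
    entry_events = list(list(domain = "condition", concept_set_id = 1L, occurrence = "all")),
    prior_observation_days = 0L
  )
  e <- entries_of(list(1L, 1L, "2011-01-01", "2012-12-31"))
  br <- index_event_breakdown(e, defn, st)
  expect_setequal(br$concept_id, c(10L, 20L))  # day-before concept not counted
  expect_true(all(br$entry_count == 1L))
  expect_true(all(br$entry_count >= br$subject_count))
})

test_that("index event breakdown equals a nested-loop join on random toy stores", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 15
    persons <- tibble::tibble(person_id = 1:n, sex = "MALE", year_of_birth = 1970L)
    periods <- tibble::tibble(person_id = 1:n, start_date = as.Date("2010-01-01"),
                              end_date = as.Date("2013-12-31"))
    ev <- tibble::tibble(
      person_id = sample(1:n, 80, replace = TRUE),
      concept_id = sample(c(10L, 20L, 30L), 80, replace = TRUE),
      domain = "condition",
      event_date = as.Date("2010-01-01") + sample(0:1400, 80, replace = TRUE),
      end_date = as.Date(NA)
    )
    st <- toy_store(persons, periods, ev, vocab = flat_vocab(c(10L, 20L, 30L)))
    defn <- cohort_definition(
      cohort_id = 1L, name = "t",
      concept_sets = list(concept_set(1, "s", tibble::tibble(
        concept_id = c(10L, 20L), include_descendants = FALSE, is_excluded = FALSE))),
      entry_events = list(list(domain = "condition", concept_set_id = 1L,
                               occurrence = "all")),
      prior_observation_days = 0L
    )
    ci <- instantiate_cohort(defn, st)
    br <- index_event_breakdown(ci, defn, st)
    # oracle: nested loops over entries x events
    exp <- list()
    for (i in seq_len(nrow(ci$entries))) {
      sid <- ci$entries$subject_id[i]
      d <- ci$entries$cohort_start_date[i]
      cids <- unique(ev$concept_id[ev$person_id == sid & ev$event_date == d &
                                     ev$concept_id %in% c(10L, 20L)])
      for (cc in cids) exp[[length(exp) + 1]] <- data.frame(concept_id = cc, sid = sid)
    }
    if (length(exp) > 0) {
      exp_df <- do.call(rbind, exp)
      exp_counts <- stats::aggregate(list(entry_count = exp_df$sid),
                                     list(concept_id = exp_df$concept_id), length)
      got <- as.data.frame(br[order(br$concept_id), c("concept_id", "entry_count")])
      rownames(got) <- NULL
      expect_equal(got, exp_counts[order(exp_counts$concept_id), ],
                   ignore_attr = TRUE, info = paste("seed", seed))
    } else {
      expect_equal(nrow(br), 0)
    }
  }
})

test_that("visit context windows follow the stated classification", {
  idx <- as.Date("2012-06-15")
  mk_visit <- function(s_off, e_off, cat = "outpatient") {
    tibble::tibble(person_id = 1L, visit_category = cat,
                   start_date = idx + s_off, end_date = idx + e_off)
  }
  st_for <- function(v) toy_store(
    tibble::tibble(person_id = 1L, sex = "FEMALE", year_of_birth = 1980L),
    tibble::tibble(person_id = 1L, start_date = as.Date("2010-01-01"),
                   end_date = as.Date("2014-12-31")),
    visits = v
  )
  e <- entries_of(list(1L, 1L, as.character(idx), "2014-12-31"))
  ctx <- function(v) {
    out <- visit_context(e, st_for(v))
    if (nrow(out) == 0) NA_character_ else out$context
  }
  expect_equal(ctx(mk_visit(-40, -10)), "before")
  expect_equal(ctx(mk_visit(-5, 2)), "during")
  expect_equal(ctx(mk_visit(0, 3)), "simultaneous")
  expect_equal(ctx(mk_visit(1, 4)), "after")
  expect_equal(ctx(mk_visit(-40, -31)), NA_character_)  # concluded too early
  expect_equal(ctx(mk_visit(31, 35)), NA_character_)    # commenced too late
  expect_equal(ctx(mk_visit(-31, -31)), NA_character_)
  expect_equal(ctx(mk_visit(-30, -30)), "before")
  expect_equal(ctx(mk_visit(30, 30)), "after")
  # precedence: a visit spanning index is during, never before
  expect_equal(ctx(mk_visit(-10, 0)), "during")
})

test_that("each entry-visit pair maps to at most one context on random fixtures", {
  set.seed(11)
  idx <- as.Date("2012-06-15")
  offs <- tibble::tibble(s = sample(-60:60, 300, replace = TRUE))
  offs$e <- offs$s + sample(0:30, 300, replace = TRUE)
  preds <- with(offs, cbind(
    simultaneous = s == 0,
    during = s < 0 & e >= 0,
    before = e >= -30 & e <= -1,
    after = s >= 1 & s <= 30
  ))
  # precedence resolves multi-hits; raw predicates overlap only where the
  # precedence order is defined
  first_hit <- apply(preds, 1, function(r) if (any(r)) names(which(r))[1] else NA)
  v <- tibble::tibble(person_id = 1L, visit_category = "outpatient",
                      start_date = idx + offs$s, end_date = idx + offs$e)
  st <- toy_store(
    tibble::tibble(person_id = 1L, sex = "FEMALE", year_of_birth = 1980L),
    tibble::tibble(person_id = 1L, start_date = as.Date("2010-01-01"),
                   end_date = as.Date("2014-12-31")),
    visits = v
  )
  e <- entries_of(list(1L, 1L, as.character(idx), "2014-12-31"))
  out <- visit_context(e, st)
  # distinct-subject counts: one subject, so each present context counts 1
  expect_true(all(out$subject_count == 1L))
  expect_setequal(out$context, unique(stats::na.omit(first_hit)))
})

test_that("cohort overlap is subject-level set algebra with conservation", {
  a <- entries_of(list(1L, 1L, "2010-01-01", "2010-12-31"),
                  list(1L, 2L, "2010-01-01", "2010-12-31"))
  ov_same <- cohort_overlap(a, dplyr::mutate(a, cohort_id = 2L))
  expect_equal(unlist(ov_same[c("n_both", "n_only_a", "n_only_b")]),
               c(n_both = 2L, n_only_a = 0L, n_only_b = 0L))
  b <- entries_of(list(2L, 3L, "2010-01-01", "2010-12-31"))
  ov_disj <- cohort_overlap(a, b)
  expect_equal(unlist(ov_disj[c("n_both", "n_only_a", "n_only_b")]),
               c(n_both = 0L, n_only_a = 2L, n_only_b = 1L))
  for (seed in 1:10) {
    set.seed(seed)
    sa <- sample(1:50, sample(5:30, 1))
    sb <- sample(1:50, sample(5:30, 1))
    ea <- tibble::tibble(cohort_id = 1L, subject_id = sa,
                         cohort_start_date = as.Date("2010-01-01"),
                         cohort_end_date = as.Date("2010-12-31"))
    eb <- tibble::tibble(cohort_id = 2L, subject_id = sb,
                         cohort_start_date = as.Date("2010-01-01"),
                         cohort_end_date = as.Date("2010-12-31"))
    ov <- cohort_overlap(ea, eb)
    expect_equal(ov$n_both, length(intersect(sa, sb)))
    expect_equal(ov$n_only_a, length(setdiff(sa, sb)))
    expect_equal(ov$n_only_b, length(setdiff(sb, sa)))
    expect_equal(ov$n_both + ov$n_only_a + ov$n_only_b, length(union(sa, sb)))
  }
})

char_store <- function(ev, n = 4L) {
  toy_store(
    tibble::tibble(person_id = seq_len(n), sex = "FEMALE", year_of_birth = 1980L),
    tibble::tibble(person_id = seq_len(n), start_date = as.Date("2008-01-01"),
                   end_date = as.Date("2014-12-31")),
    ev, vocab = flat_vocab(unique(ev$concept_id))
  )
}

test_that("characterization boundary offsets land in the printed windows", {
  idx <- as.Date("2012-06-15")
  e <- entries_of(list(1L, 1L, as.character(idx), "2014-12-31"))
  for (off in c(-365, -31, -30, -1, 0, 1, 30, 31, 365)) {
    ev <- tibble::tibble(person_id = 1L, concept_id = 10L, domain = "condition",
                         event_date = idx + off, end_date = as.Date(NA))
    ch <- characterize(e, char_store(ev, n = 1L))
    got <- ch[ch$covariate_type == "event", c("window_start", "window_end")]
    exp_win <- if (off >= -365 && off <= -31) c(-365, -31)
    else if (off >= -30 && off <= -1) c(-30, -1)
    else if (off == 0) c(0, 0)
    else if (off >= 1 && off <= 30) c(1, 30)
    else c(31, 365)
    expect_equal(nrow(got), 1, info = paste("offset", off))
    expect_equal(unlist(got), c(window_start = exp_win[1], window_end = exp_win[2]),
                 info = paste("offset", off))
  }
})

test_that("characterization proportions use subject counts with per-subject dedup", {
  idx <- as.Date("2012-06-15")
  ev <- tibble::tibble(person_id = c(1L, 1L), concept_id = 10L, domain = "condition",
                       event_date = c(idx - 10, idx - 5), end_date = as.Date(NA))
  e <- entries_of(list(1L, 1L, as.character(idx), "2014-12-31"),
                  list(1L, 2L, as.character(idx), "2014-12-31"),
                  list(1L, 3L, as.character(idx), "2014-12-31"),
                  list(1L, 4L, as.character(idx), "2014-12-31"))
  ch <- characterize(e, char_store(ev))
  row <- ch[ch$covariate_type == "event" & ch$window_start == -30, ]
  expect_equal(row$n_subjects, 1L)
  expect_equal(row$proportion, 0.25)
  # duplicating the event does not change the proportion
  ev2 <- dplyr::bind_rows(ev, ev)
  ch2 <- characterize(e, char_store(ev2))
  expect_equal(ch2[ch2$covariate_type == "event" & ch2$window_start == -30, ]$proportion, 0.25)
  # demographics under the index window
  demo <- ch[ch$covariate_type == "demographic", ]
  expect_true(all(demo$window_start == 0 & demo$window_end == 0))
  expect_true("sex: FEMALE" %in% demo$covariate_name)
  expect_true("age_group: 30-39" %in% demo$covariate_name)
})

test_that("characterization equals a brute-force per-subject scan on random fixtures", {
  windows <- list(c(-365, -31), c(-30, -1), c(0, 0), c(1, 30), c(31, 365))
  for (seed in 1:8) {
    set.seed(seed)
    n <- 12
    idx_dates <- as.Date("2011-01-01") + sample(0:700, n, replace = TRUE)
    e <- tibble::tibble(cohort_id = 1L, subject_id = 1:n,
                        cohort_start_date = idx_dates,
                        cohort_end_date = as.Date("2014-12-31"))
    ev <- tibble::tibble(
      person_id = sample(1:n, 150, replace = TRUE),
      concept_id = sample(c(10L, 20L, 30L), 150, replace = TRUE),
      domain = "condition",
      event_date = as.Date("2010-01-01") + sample(0:1500, 150, replace = TRUE),
      end_date = as.Date(NA)
    )
    ch <- characterize(e, char_store(ev, n = n), windows = windows)
    ch_ev <- ch[ch$covariate_type == "event", ]
    for (w in windows) {
      for (cc in c(10L, 20L, 30L)) {
        n_exp <- 0L
        for (sid in 1:n) {
          offs <- as.integer(ev$event_date[ev$person_id == sid & ev$concept_id == cc] -
                               idx_dates[sid])
          if (any(offs >= w[1] & offs <= w[2])) n_exp <- n_exp + 1L
        }
        got <- ch_ev[ch_ev$window_start == w[1] & ch_ev$window_end == w[2] &
                       ch_ev$concept_id == cc, ]
        if (n_exp == 0) {
          expect_equal(nrow(got), 0)
        } else {
          expect_equal(got$n_subjects, n_exp,
                       info = sprintf("seed %d w %d..%d c %d", seed, w[1], w[2], cc))
          expect_equal(got$proportion, n_exp / n)
        }
      }
    }
  }
})

test_that("SMD is zero at equality, antisymmetric, and matches its closed form", {
  expect_equal(binary_smd(0.3, 0.3), 0)
  expect_equal(binary_smd(0.5, 0.2), 0.3 / sqrt((0.25 + 0.16) / 2))
  expect_true(abs(binary_smd(0.5, 0.2) - 0.6626) < 5e-4)
  expect_true(is.na(binary_smd(0, 0)))
  expect_true(is.na(binary_smd(1, 1)))
  expect_equal(binary_smd(0, 1), -Inf)
  set.seed(3)
  p1 <- stats::runif(200); p2 <- stats::runif(200)
  expect_equal(binary_smd(p1, p2), -binary_smd(p2, p1))
})

test_that("balance rows treat one-sided covariates as zero and flip under swap", {
  idx <- as.Date("2012-06-15")
  ev <- tibble::tibble(person_id = 1:2, concept_id = c(10L, 20L), domain = "condition",
                       event_date = idx - 5, end_date = as.Date(NA))
  st <- char_store(ev)
  et <- entries_of(list(1L, 1L, as.character(idx), "2014-12-31"),
                   list(1L, 2L, as.character(idx), "2014-12-31"))
  ec <- entries_of(list(2L, 3L, as.character(idx), "2014-12-31"),
                   list(2L, 4L, as.character(idx), "2014-12-31"))
  cht <- characterize(et, st)
  chc <- characterize(ec, st)
  bal <- compare_characterizations(cht, chc)
  r10 <- bal[!is.na(bal$concept_id) & bal$concept_id == 10L & bal$window_start == -30, ]
  expect_equal(r10$p_target, 0.5)
  expect_equal(r10$p_comparator, 0)  # absent on comparator side -> 0
  swapped <- compare_characterizations(chc, cht)
  s10 <- swapped[!is.na(swapped$concept_id) & swapped$concept_id == 10L &
                   swapped$window_start == -30, ]
  expect_equal(s10$smd, -r10$smd)
  # mismatched windows refuse
  ch_alt <- characterize(et, st, windows = list(c(-10, -1)))
  expect_error(compare_characterizations(ch_alt, chc), "window")
})

test_that("relative difference reproduces half-up one-decimal rounding", {
  expect_equal(relative_difference(1000, 1000), 0)
  expect_equal(relative_difference(200, 100), 50)
  expect_equal(relative_difference(1000, 625), 37.5)
  expect_equal(relative_difference(1000, 625), 37.5)
  expect_error(relative_difference(0, 5), "count_simple")
})
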