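# Brute-force oracles, independent of the implementation paths they check.

# Per-day risk-set enumeration of stratified incidence. Returns a function
# of a strata subset so one enumeration serves every combination.
oracle_incidence_enumeration <- function(store, entries, washout_days = 0L) {
  persons <- store$persons
  periods <- store$observation_periods
  day_rows <- list()
  case_rows <- list()
  for (i in seq_len(nrow(persons))) {
    pid <- persons$person_id[i]
    pp <- periods[periods$person_id == pid, , drop = FALSE]
    if (nrow(pp) == 0) next
    fe_all <- entries$cohort_start_date[entries$subject_id == pid]
    fe <- if (length(fe_all) > 0) min(fe_all) else as.Date(NA)
    days <- as.Date(integer(), origin = "1970-01-01")
    for (j in seq_len(nrow(pp))) {
      d <- seq(pp$start_date[j], pp$end_date[j], by = "day")
      d <- d[d >= pp$start_date[j] + washout_days]
      days <- c(days, d)
    }
    if (!is.na(fe)) days <- days[days <= fe]
    if (length(days) == 0) next
    yr <- as.integer(format(days, "%Y"))
    yob <- persons$year_of_birth[i]
    age <- yr - yob
    band <- ifelse(is.na(age) | age < 0, NA_character_,
                   paste0(floor(age / 10) * 10, "-", floor(age / 10) * 10 + 9))
    day_rows[[length(day_rows) + 1]] <-
      data.frame(sex = persons$sex[i], calendar_year = yr, age_group = band,
                 stringsAsFactors = FALSE)
    if (!is.na(fe) && fe %in% days) {
      fy <- as.integer(format(fe, "%Y"))
      fage <- fy - yob
      fband <- if (is.na(fage) || fage < 0) NA_character_ else
        paste0(floor(fage / 10) * 10, "-", floor(fage / 10) * 10 + 9)
      case_rows[[length(case_rows) + 1]] <-
        data.frame(sex = persons$sex[i], calendar_year = fy, age_group = fband,
                   stringsAsFactors = FALSE)
    }
  }
  days_df <- if (length(day_rows) > 0) do.call(rbind, day_rows) else
    data.frame(sex = character(), calendar_year = integer(), age_group = character())
  cases_df <- if (length(case_rows) > 0) do.call(rbind, case_rows) else
    data.frame(sex = character(), calendar_year = integer(), age_group = character())

  function(by) {
    d <- days_df
    k <- cases_df
    if ("age_group" %in% by) {
      d <- d[!is.na(d$age_group), , drop = FALSE]
      k <- k[!is.na(k$age_group), , drop = FALSE]
    }
    if (length(by) == 0) {
      out <- data.frame(person_years = nrow(d) / 365.25, cases = nrow(k))
    } else if (nrow(d) == 0) {
      out <- stats::setNames(
        data.frame(matrix(nrow = 0, ncol = length(by) + 2)),
        c(by, "person_years", "cases"))
    } else {
      py <- stats::aggregate(list(n_days = rep(1L, nrow(d))), d[, by, drop = FALSE], sum)
      cs <- if (nrow(k) > 0) {
        stats::aggregate(list(cases = rep(1L, nrow(k))), k[, by, drop = FALSE], sum)
      } else {
        cbind(py[0, by, drop = FALSE], cases = integer())
      }
      out <- merge(py, cs, by = by, all.x = TRUE)
      out$cases[is.na(out$cases)] <- 0L
      out$person_years <- out$n_days / 365.25
      out$n_days <- NULL
    }
    out
  }
}

# Full comparison against incidence_rates() across every strata combination.
# Returns a list(ok=, max_py_err=, detail=).
check_incidence_against_oracle <- function(store, entries, washout_days = 0L) {
  pkg <- phenodiag::incidence_rates(entries, store, by_age = TRUE, by_sex = TRUE,
                                    by_year = TRUE, washout_days = washout_days)
  oracle <- oracle_incidence_enumeration(store, entries, washout_days)
  dims <- c("age_group", "sex", "calendar_year")
  combos <- unlist(lapply(0:3, function(k) utils::combn(dims, k, simplify = FALSE)),
                   recursive = FALSE)
  max_err <- 0
  for (by in combos) {
    exp <- oracle(by)
    exp <- exp[exp$person_years > 0, , drop = FALSE]
    absent <- setdiff(dims, by)
    got <- pkg
    for (a in absent) got <- got[is.na(got[[a]]), , drop = FALSE]
    for (b in by) got <- got[!is.na(got[[b]]), , drop = FALSE]
    if (nrow(got) != nrow(exp)) {
      return(list(ok = FALSE, max_py_err = Inf,
                  detail = sprintf("row count mismatch for {%s}: got %d, expected %d",
                                   paste(by, collapse = ","), nrow(got), nrow(exp))))
    }
    key <- function(df) {
      if (length(by) == 0) rep("", nrow(df)) else
        do.call(paste, c(lapply(by, function(b) df[[b]]), sep = "|"))
    }
    got <- got[order(key(got)), , drop = FALSE]
    exp <- exp[order(key(exp)), , drop = FALSE]
    if (!identical(as.integer(got$cases), as.integer(exp$cases))) {
      return(list(ok = FALSE, max_py_err = Inf,
                  detail = sprintf("case mismatch for {%s}", paste(by, collapse = ","))))
    }
    err <- if (nrow(got) == 0) 0 else max(abs(got$person_years - exp$person_years))
    max_err <- max(max_err, err)
    if (err > 1e-9) {
      return(list(ok = FALSE, max_py_err = err,
                  detail = sprintf("person-years off for {%s}", paste(by, collapse = ","))))
    }
  }
  list(ok = TRUE, max_py_err = max_err, detail = "")
}

# Naive reachability oracle for concept-set resolution over a raw edge list.
oracle_resolve <- function(items, edges) {
  reach <- function(id) {
    out <- id
    frontier <- id
    repeat {
      nxt <- setdiff(edges$child_id[edges$parent_id %in% frontier], out)
      if (length(nxt) == 0) break
      out <- c(out, nxt)
      frontier <- nxt
    }
    out
  }
  expand <- function(sub) {
    if (nrow(sub) == 0) return(integer())
    unique(unlist(lapply(seq_len(nrow(sub)), function(i) {
      if (sub$include_descendants[i]) reach(sub$concept_id[i]) else sub$concept_id[i]
    })))
  }
  sort(setdiff(expand(items[!items$is_excluded, , drop = FALSE]),
               expand(items[items$is_excluded, , drop = FALSE])))
}

# BFS over inverted edges: nearest designated ancestor (ties -> smallest id).
oracle_rollup <- function(concept_ids, edges, groups) {
  parent_of <- split(edges$parent_id, edges$child_id)
  vapply(concept_ids, function(cid) {
    level <- cid
    seen <- cid
    repeat {
      hit <- sort(intersect(level, groups))
      if (length(hit) > 0) return(hit[1])
      nxt <- setdiff(unique(unlist(parent_of[as.character(level)])), seen)
      if (length(nxt) == 0) return(cid)
      seen <- c(seen, nxt)
      level <- nxt
    }
  }, integer(1))
}

# Per-day membership oracle for era collapse.
oracle_collapse <- function(starts, ends, gap_days) {
  days <- sort(unique(unlist(Map(function(s, e) seq(as.integer(s), as.integer(e)),
                                 starts, ends))))
  breaks <- which(diff(days) > gap_days + 1)
  s_idx <- c(1, breaks + 1)
  e_idx <- c(breaks, length(days))
  list(start = as.Date(days[s_idx], origin = "1970-01-01"),
       end = as.Date(days[e_idx], origin = "1970-01-01"))
}
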