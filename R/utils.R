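# Internal helpers shared across modules. All date arithmetic is in whole
# days on base Date objects (OMOP dates are day-granular).

#' Merge overlapping or near-overlapping day intervals
#'
#' Intervals are closed `[start, end]` in days. Two intervals are merged when
#' the gap between them is at most `gap_days` (gap = next start - previous
#' end - 1, so abutting intervals have gap 0).
#'
#' @param starts,ends Date vectors of equal length.
#' @param gap_days Non-negative integer; maximum gap that still merges.
#' @return A list with Date vectors `start` and `end`, sorted, disjoint.
#' @noRd
merge_day_intervals <- function(starts, ends, gap_days = 0L) {
  stopifnot(length(starts) == length(ends))
  if (length(starts) == 0L) {
    return(list(start = as.Date(character()), end = as.Date(character())))
  }
  ord <- order(starts, ends)
  starts <- starts[ord]
  ends <- ends[ord]
  out_s <- starts[1]
  out_e <- ends[1]
  k <- 1L
  for (i in seq_along(starts)[-1]) {
    if (as.integer(starts[i]) <= as.integer(out_e[k]) + gap_days + 1L) {
      if (ends[i] > out_e[k]) out_e[k] <- ends[i]
    } else {
      k <- k + 1L
      out_s[k] <- starts[i]
      out_e[k] <- ends[i]
    }
  }
  list(start = out_s, end = out_e)
}

#' Round half away from zero
#'
#' Unlike [round()], ties go away from zero (so 0.15 -> 0.2 at one digit),
#' matching how the published relative-difference percentages are printed.
#' @noRd
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Ten-year age band label for an integer age
#' @noRd
age_band_label <- function(age) {
  band <- floor(age / 10)
  lab <- paste0(band * 10, "-", band * 10 + 9)
  lab[is.na(age) | age < 0] <- NA_character_
  lab
}

#' Parse ISO-8601 date columns strictly, reporting row coordinates on failure
#' @noRd
parse_iso_dates <- function(x, table, column) {
  if (inherits(x, "Date")) return(x)
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- which(is.na(d) & !is.na(x) & !(as.character(x) == ""))
  if (length(bad) > 0) {
    abort(sprintf(
      "Unparseable date(s) in %s$%s at row(s) %s (expected YYYY-MM-DD).",
      table, column, paste(head(bad, 5), collapse = ", ")
    ))
  }
  d
}

#' Days between calendar dates, inclusive of both endpoints
#' @noRd
inclusive_days <- function(start, end) as.integer(end) - as.integer(start) + 1L

DAYS_PER_YEAR <- 365.25

#' md5 digest of a character scalar (via a temp file; base R only)
#' @noRd
md5_string <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(enc2utf8(paste(x, collapse = "\n")), tf, useBytes = TRUE)
  unname(tools::md5sum(tf))
}
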