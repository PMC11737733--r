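---
title: "Evaluating phenotype algorithms with population-level diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating phenotype algorithms with population-level diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenodiag)
```

## The evaluation model

A phenotype algorithm (PA) classifies person-time: it decides who has the
condition and from when. Its errors come in three flavours — sensitivity
(true cases missed), specificity (non-cases included) and index-date
misclassification (the right person entered on the wrong date, typically
because treatment or symptoms are recorded before the diagnosis code).
`phenodiag` estimates none of these directly; instead it computes aggregate
statistics whose *patterns* are diagnostic. A rate far from external
expectation, entry driven by a single code, heavy treatment prevalence in
the month *before* index, or a large standardized difference between two
candidate PAs each point at a specific error type. The package's job is to
compute those statistics correctly, reproducibly, and in a form that can
leave a data site without privacy risk.

## Data model and conventions

All inputs are day-granular; every date is a calendar day and all
arithmetic is in integer days. On construction of a store:

* Overlapping or abutting observation periods of one person are merged into
  a canonical non-overlapping set (the raw rows are kept for audit). A
  person may still hold several disjoint periods; each is treated as an
  independent stretch of continuous observation.
* Event domain tables are merged into one append-ordered event view with a
  stable surrogate `event_id`, so any downstream tie-break is reproducible.
* Persons without a birth year stay in the store and in all diagnostics
  except age-stratified ones, where they are excluded with a logged count.
  Dropping them entirely would silently bias the non-age diagnostics.

## Cohort instantiation

A definition lists concept sets, entry events, a prior-observation
(washout) requirement, ordered inclusion rules, and an exit strategy.
Resolution of a concept set is the union of its included items (plus
descendants where flagged) minus the expansion of its excluded items;
exclusion wins over inclusion for an item listed as both, following the
convention of the wider OMOP tooling ecosystem. This precedence was a
genuinely open choice — the alternative (inclusion wins) breaks the
monotonicity property that adding an exclusion can only shrink a set.

The index date is the subject's *earliest* event matching any entry event
that lies inside an observation period starting at least
`prior_observation_days` earlier. "Continuous observation prior to index"
is read strictly: the enclosing normalized period itself must provide the
full run-up, with no gap tolerance beyond period normalization. An entry
event with `occurrence = "first_ever"` restricts candidates to the
subject's earliest event of that set in the whole store *before* washout
filtering — so a first-ever event inside the washout disqualifies the
subject rather than deferring to a later event.

Inclusion rules are closed windows in days relative to index (day 0 is the
index date; "within 0 to 90 days" includes day 90 and excludes day 91),
with `at_least` / `at_most` / `exactly` occurrence comparators; exclusions
are `at_most 0` rules. Unbounded offsets are `±Inf` (`null`/"inf" in the
JSON schema). One entry per subject is emitted; disjunctive entry arms that
should each contribute entries are expressed as separate definitions
combined with `union_cohorts()` (earliest start wins, eras collapsed at gap
0). Instantiation is fully deterministic: no randomness anywhere in the
engine.

Attrition is sequential: row 0 counts entry-event survivors, row *i* the
survivors of rule *i* applied to the survivors of rule *i−1*. Independent
per-rule contribution counts would be a useful extension but are not
emitted.

## Incidence rates

The denominator population is every person with any observation time.
Conventions, chosen once and applied identically in the engine, the ground
truth computation and the test oracles:

* slices are counted in inclusive days (`end − start + 1`);
* person-years use a 365.25-day year;
* a person's at-risk time is right-censored at their *first* cohort entry,
  with the entry day itself at risk (a person entering on their first
  observed day contributes exactly 1/365.25 person-years);
* `washout_days` trims the start of every observation period, and a first
  entry inside the trimmed span is not a qualifying case;
* person-time is split at calendar-year boundaries; age is
  `calendar_year − year_of_birth`, banded into 10-year groups — day-precise
  birth dates are often absent from real sources, so year arithmetic is the
  honest resolution;
* repeat entries never add cases: incidence is first-occurrence incidence.
  Whether repeat entries should count is a real ambiguity in the field; the
  first-entry convention is the epidemiologically standard one and the
  switch is exposed through era-collapse upstream.

Rows are produced for *every* subset of the requested strata dimensions, so
marginal rates and fully stratified rates come from one call and sum
consistently (cases exactly; person-years to floating-point precision).
Strata with zero person-time are omitted. The engine is verified against a
literal per-day risk-set enumeration on randomized small stores, including
multi-period persons, missing birth years and entries outside observation.

## Windows, visit context and characterization

The five characterization windows `[-365,-31], [-30,-1], [0,0], [1,30],
[31,365]` are closed intervals; boundary offsets −31/−30 and 30/31 belong
to the outer/inner windows respectively. Each subject is anchored on their
*first* cohort entry only, so a subject counts at most once per
(window, concept) cell and proportions are invariant to duplicated events.
Anchoring on all entries would double-count subjects across windows; the
first-entry choice is ours and is the main place a re-implementation could
legitimately differ. With roll-up enabled, every observed concept is also
reported once under its nearest designated hierarchy ancestor (ties break
to the smallest concept id), alongside — not instead of — its raw row.

Visit context classifies each (entry, visit) pair into exactly one of
`simultaneous` (visit starts on index), `during` (starts before, ends on or
after index), `before` (ends within 30 days before index) or `after`
(starts within 30 days after index), applying that precedence order. The
precedence is an artifact decision: the category texts do not say whether a
visit may count twice, and a partition keeps distinct-subject counts
interpretable.

For binary prevalences the standardized difference is
`(p_t − p_c) / sqrt((p_t(1−p_t) + p_c(1−p_c))/2)`, signed, antisymmetric
under cohort swap, `NA` when both proportions are 0 or both 1 (no variance,
no contrast), and `±Inf` in the degenerate 0-vs-1 case. Covariates absent
from one side are proportion 0 there. Continuous covariates are out of the
default set: the diagnostics here are prevalence-based, and mixing variance
conventions would blur the SMD's interpretation.

## Results model and censoring

The bundle is a fixed, versioned schema of named tables; person-level
identifiers are rejected at the boundary by schema. Censoring replaces any
count `0 < c < k` with the sentinel `−k` — the negative-threshold encoding
lets a consumer distinguish "censored" from "zero" and recover the policy —
and nulls derived proportions/rates rather than recomputing them from the
sentinel, which would allow back-calculation. Zero passes through; the
operation is idempotent; `k = 5` is the default floor, configurable and
recorded in the metadata table. Exports are plain CSV with a JSON manifest
(row counts, md5 digests); numeric derived values are rounded to 5
significant digits at serialization only, except the relative-difference
statistic, which is defined with half-up rounding to one decimal. The run
timestamp lives in `run_metadata.json`, outside the digested tables, so
identical runs produce identical manifests. Merging concatenates rows
keyed by source name — never aggregates across sources — and demands
distinct source names and equal schema versions.

## The synthetic generator

`generate_source()` emulates, per person: one observation period with a
random entry in the first 30% of the calendar span and exit uniform between
roughly a year later and the span end; a disease onset drawn from an
exponential waiting time at the configured hazard (per-day hazard =
rate/1000/365.25, modulated by sex and age-band multipliers); a diagnosis
code at onset + coding lag (constant or geometric); with probability
`p_treatment_before_code` a treatment code at the true onset — i.e. before
the coded diagnosis, the mechanism behind index-date misclassification —
and otherwise within 30 days after the coded diagnosis; an optional
confirmatory repeat diagnosis 30–365 days later; symptom codes shortly
before onset; Poisson background noise across all four event domains; and
a visit attached to each event by category probabilities. All draws consume
one RNG stream keyed by `seed`, in documented order, so generation is
exactly reproducible. Two presets ship: `sle_like` (female-skewed onset in
younger adults, long coding lag, substantial treatment-before-code mass)
and `ad_like` (elderly onset, dementia codes, suited to simple-vs-
restrictive comparisons).

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: realistic code frequencies, multiple observation
periods per person, correlated comorbidity structure, provider or household
clustering, lab-value trajectories, or vocabulary mapping noise. The
generator's role is ground truth for engine verification and plausible
substrate for end-to-end runs, not epidemiological realism. Ground truth
(onset dates, per-event provenance tags) is kept on a side channel that the
diagnostics path never reads.

## Numerical choices and degenerate inputs

* Empty cohorts are data, not errors: instantiation on an empty store
  yields zero entries with all-zero attrition; diagnostics on empty inputs
  yield empty (or zero-count) tables.
* An entry outside any observation period is excluded from time
  distributions with a logged count, and censors incidence person-time
  without contributing a case.
* Same-day qualifying events produce one entry; all coinciding codes remain
  visible to the index-event breakdown (multi-attribution is intentional —
  it is how treatment-before-code misclassification becomes visible).
* `relative_difference()` rounds half *away from zero* to one decimal,
  matching how such percentages are conventionally printed; base R's
  banker's rounding would differ on exact .05 boundaries.
* Quantiles in time distributions use R's default type-7 definition; the
  standard deviation of a single value is reported as 0.

## Problem sizes in the shipped checks

The test suite and acceptance script verify the incidence engine against
per-day enumeration on 200 randomized stores of 5–40 persons over 2–8
years; recover a configured onset rate of 2.0 per 1000 person-years through
a diagnosis-only definition on a 20,000-person source (agreement judged
within 3 Monte-Carlo standard errors, and the estimate must equal the
ground-truth rate computed from onset dates exactly, since zero lag makes
the two coincide); and exercise the index-misclassification monotonicity on
4,000-person sources at the two extremes of `p_treatment_before_code`.
These sizes give stable checks at interactive runtimes; the engine itself
is vectorized and comfortably handles sources one to two orders of
magnitude larger.

## Known limitations

The cohort-definition schema is deliberately smaller than the full grammar
of the ecosystem's standard cohort-definition language: no nested criteria groups, no correlated visit-context
criteria, no censoring windows, no age/demographic rules — age restrictions
must be emulated through the study population or post-filtering, and
disjunctive inclusion logic through unioned definitions. There is no
code-recommendation facility (missing/orphan code suggestion requires an
external corpus), no interactive viewer (the CSV bundle is the interface),
and no gold-standard error quantification — by design, these diagnostics
complement rather than replace validation against a reference standard.
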