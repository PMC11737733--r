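# Concept sets and hierarchy operations over the OMOP-style
# concept / concept_ancestor tables.

#' Create a concept set
#'
#' A concept set is a declarative list of vocabulary concepts, each optionally
#' expanded to its descendants and optionally excluded; together they define
#' the codes that express one clinical idea.
#'
#' @param concept_set_id Integer identifier (unique within a definition).
#' @param name Human-readable name.
#' @param items Data frame with columns `concept_id`, `include_descendants`
#'   (logical), `is_excluded` (logical).
#' @return A `concept_set` object.
#' @export
concept_set <- function(concept_set_id, name, items) {
  items <- as_tibble(items)
  stopifnot(all(c("concept_id", "include_descendants", "is_excluded") %in% names(items)))
  items$concept_id <- as.integer(items$concept_id)
  items$include_descendants <- as.logical(items$include_descendants)
  items$is_excluded <- as.logical(items$is_excluded)
  if (anyDuplicated(items$concept_id)) abort("concept_set items must have distinct concept_ids")
  if (!any(!items$is_excluded)) abort("concept_set must have at least one non-excluded item")
  structure(
    list(concept_set_id = as.integer(concept_set_id), name = as.character(name),
         items = items),
    class = "concept_set"
  )
}

# Expand one side (included or excluded) of a concept set: the items
# themselves plus descendant closure where flagged.
expand_items <- function(items, ancestors) {
  if (nrow(items) == 0) return(integer())
  direct <- items$concept_id
  with_desc <- items$concept_id[items$include_descendants]
  desc <- if (length(with_desc) > 0) {
    ancestors$descendant_concept_id[ancestors$ancestor_concept_id %in% with_desc]
  } else {
    integer()
  }
  unique(c(direct, desc))
}

#' Resolve a concept set against the concept hierarchy
#'
#' Returns the union over included items (each item plus its descendants when
#' flagged) minus the same expansion of the excluded items. Exclusions are
#' applied after all inclusions (the dominant convention in the OMOP tooling
#' ecosystem), so an item both included
#' and excluded resolves to excluded.
#'
#' @param cs A [concept_set].
#' @param ancestors Tibble of `ancestor_concept_id`, `descendant_concept_id`
#'   pairs; assumed transitively closed with reflexive pairs (as the OMOP
#'   concept_ancestor table ships). A [cdm_store] may be passed instead.
#' @param concepts Optional concept table used to verify referenced ids exist;
#'   taken from `ancestors` when that is a store.
#' @return Sorted integer vector of resolved concept_ids.
#' @export
resolve_concept_set <- function(cs, ancestors, concepts = NULL) {
  stopifnot(inherits(cs, "concept_set"))
  if (inherits(ancestors, "cdm_store")) {
    concepts <- ancestors$concepts
    ancestors <- ancestors$concept_ancestors
  }
  if (!is.null(concepts) && nrow(concepts) > 0) {
    unknown <- setdiff(cs$items$concept_id, concepts$concept_id)
    if (length(unknown) > 0) {
      abort(sprintf("Concept set '%s' references unknown concept_id(s): %s",
                    cs$name, paste(unknown, collapse = ", ")))
    }
  }
  included <- expand_items(cs$items[!cs$items$is_excluded, , drop = FALSE], ancestors)
  excluded <- expand_items(cs$items[cs$items$is_excluded, , drop = FALSE], ancestors)
  sort(setdiff(included, excluded))
}

#' Map observed concepts to designated hierarchy groups
#'
#' For characterization roll-up: each input concept maps to its *nearest*
#' designated group ancestor (fewest hops up the hierarchy); concepts with no
#' designated ancestor map to themselves. Ties at equal distance break to the
#' smallest ancestor concept_id for determinism.
#'
#' @param concept_ids Integer vector of observed concepts.
#' @param ancestors `concept_ancestor`-shaped tibble (transitively closed,
#'   reflexive), optionally with a `min_levels_of_separation` column; when the
#'   column is absent, distance is taken as 0 for the reflexive pair and 1
#'   otherwise (flat closure), which still selects a designated ancestor
#'   deterministically.
#' @param groups Integer vector of designated group concept_ids.
#' @return Tibble `concept_id`, `group_concept_id` with one row per input.
#' @export
rollup_concepts <- function(concept_ids, ancestors, groups) {
  concept_ids <- unique(as.integer(concept_ids))
  groups <- as.integer(groups)
  has_lvl <- "min_levels_of_separation" %in% names(ancestors)
  cand <- ancestors %>%
    filter(.data$descendant_concept_id %in% concept_ids,
           .data$ancestor_concept_id %in% groups) %>%
    mutate(dist = if (has_lvl) .data$min_levels_of_separation
           else ifelse(.data$ancestor_concept_id == .data$descendant_concept_id, 0L, 1L)) %>%
    group_by(.data$descendant_concept_id) %>%
    arrange(.data$dist, .data$ancestor_concept_id, .by_group = TRUE) %>%
    dplyr::slice(1) %>%
    ungroup() %>%
    select(concept_id = "descendant_concept_id", group_concept_id = "ancestor_concept_id")
  tibble(concept_id = concept_ids) %>%
    left_join(cand, by = "concept_id") %>%
    mutate(group_concept_id = dplyr::coalesce(.data$group_concept_id, .data$concept_id))
}

#' Build the transitive, reflexive closure of parent-child concept links
#'
#' @param edges Tibble with `parent_id`, `child_id` direct links (a DAG).
#' @param concept_ids All concept ids that should receive reflexive pairs.
#' @return `concept_ancestor`-shaped tibble with `min_levels_of_separation`.
#' @export
ancestor_closure <- function(edges, concept_ids) {
  concept_ids <- unique(as.integer(concept_ids))
  # dist[[as.character(desc)]][as.character(anc)] = min hops
  pairs <- tibble(
    ancestor_concept_id = concept_ids,
    descendant_concept_id = concept_ids,
    min_levels_of_separation = 0L
  )
  if (nrow(edges) > 0) {
    edges <- tibble(parent_id = as.integer(edges$parent_id),
                    child_id = as.integer(edges$child_id))
    # BFS up from every node; vocabularies here are small.
    acc <- list(pairs)
    frontier <- tibble(ancestor_concept_id = edges$parent_id,
                       descendant_concept_id = edges$child_id,
                       min_levels_of_separation = 1L)
    seen <- pairs %>% select(1, 2)
    lvl <- 1L
    while (nrow(frontier) > 0 && lvl < 50L) {
      frontier <- anti_join(frontier, seen,
                            by = c("ancestor_concept_id", "descendant_concept_id"))
      if (nrow(frontier) == 0) break
      acc[[length(acc) + 1]] <- frontier
      seen <- bind_rows(seen, frontier %>% select(1, 2))
      frontier <- frontier %>%
        inner_join(edges, by = c("descendant_concept_id" = "parent_id"),
                   relationship = "many-to-many") %>%
        distinct(.data$ancestor_concept_id, descendant_concept_id = .data$child_id) %>%
        mutate(min_levels_of_separation = lvl + 1L)
      lvl <- lvl + 1L
    }
    pairs <- bind_rows(acc) %>%
      group_by(.data$ancestor_concept_id, .data$descendant_concept_id) %>%
      summarise(min_levels_of_separation = min(.data$min_levels_of_separation),
                .groups = "drop")
  }
  arrange(pairs, .data$ancestor_concept_id, .data$descendant_concept_id)
}

#' Miniature synthetic vocabulary
#'
#' A three-level, ~200-concept vocabulary with SNOMED-like condition groups
#' (an autoimmune branch containing lupus codes, a dementia branch with
#' Alzheimer/vascular/Lewy-body/Pick subtypes, stroke, symptom groups),
#' RxNorm-like drug classes (antimalarial/steroid/immunosuppressant,
#' cholinesterase inhibitors and memantine), procedures, measurements, visit
#' concepts and background "noise" codes. Used by the synthetic-data
#' generator and the shipped example cohort definitions; real OMOP
#' vocabularies are supported but never required.
#'
#' @return List with tibbles `concepts` (concept table), `concept_ancestors`
#'   (closed hierarchy) and `edges` (the direct links).
#' @export
synthetic_vocabulary <- function() {
  cpt <- function(id, name, domain, vocab) {
    tibble(concept_id = as.integer(id), concept_name = name,
           domain_id = domain, vocabulary_id = vocab)
  }
  concepts <- bind_rows(
    # Condition hierarchy
    cpt(1000, "Autoimmune connective tissue disorder", "condition", "SNOMED"),
    cpt(1100, "Lupus erythematosus", "condition", "SNOMED"),
    cpt(1101, "Systemic lupus erythematosus", "condition", "SNOMED"),
    cpt(1102, "Lupus nephritis", "condition", "SNOMED"),
    cpt(1103, "Cutaneous lupus erythematosus", "condition", "SNOMED"),
    cpt(1104, "Drug-induced lupus", "condition", "SNOMED"),
    cpt(1105, "SLE, unspecified (coded)", "condition", "ICD10"),
    cpt(1200, "Musculoskeletal symptom", "condition", "SNOMED"),
    cpt(1201, "Joint pain", "condition", "SNOMED"),
    cpt(1202, "Back pain", "condition", "SNOMED"),
    cpt(1210, "Inflammatory dermatosis", "condition", "SNOMED"),
    cpt(1211, "Rash", "condition", "SNOMED"),
    cpt(1212, "Photosensitive eruption", "condition", "SNOMED"),
    cpt(1220, "Endocarditis", "condition", "SNOMED"),
    cpt(2000, "Dementia", "condition", "SNOMED"),
    cpt(2100, "Alzheimer's disease", "condition", "SNOMED"),
    cpt(2101, "Alzheimer's disease, early onset", "condition", "SNOMED"),
    cpt(2102, "Alzheimer's disease, late onset", "condition", "SNOMED"),
    cpt(2200, "Vascular dementia", "condition", "SNOMED"),
    cpt(2201, "Multi-infarct dementia", "condition", "SNOMED"),
    cpt(2300, "Lewy body disease", "condition", "SNOMED"),
    cpt(2400, "Pick's disease", "condition", "SNOMED"),
    cpt(2450, "Dementia symptom", "condition", "SNOMED"),
    cpt(2451, "Memory impairment", "condition", "SNOMED"),
    cpt(2452, "Confusion", "condition", "SNOMED"),
    cpt(2500, "Cerebrovascular accident", "condition", "SNOMED"),
    cpt(2501, "Ischemic stroke", "condition", "SNOMED"),
    # Drug hierarchy
    cpt(4000, "Immunomodulating agent", "drug", "RxNorm"),
    cpt(4100, "Antimalarial", "drug", "RxNorm"),
    cpt(4101, "Hydroxychloroquine", "drug", "RxNorm"),
    cpt(4200, "Systemic corticosteroid", "drug", "RxNorm"),
    cpt(4201, "Prednisone", "drug", "RxNorm"),
    cpt(4202, "Methylprednisolone", "drug", "RxNorm"),
    cpt(4300, "Immunosuppressant", "drug", "RxNorm"),
    cpt(4301, "Methotrexate", "drug", "RxNorm"),
    cpt(4302, "Cyclophosphamide", "drug", "RxNorm"),
    cpt(4500, "Anti-dementia agent", "drug", "RxNorm"),
    cpt(4510, "Cholinesterase inhibitor", "drug", "RxNorm"),
    cpt(4511, "Donepezil", "drug", "RxNorm"),
    cpt(4512, "Rivastigmine", "drug", "RxNorm"),
    cpt(4520, "NMDA antagonist", "drug", "RxNorm"),
    cpt(4521, "Memantine", "drug", "RxNorm"),
    # Procedures / measurements
    cpt(5000, "Diagnostic procedure", "procedure", "SNOMED"),
    cpt(5100, "Cognitive assessment", "procedure", "SNOMED"),
    cpt(5101, "Mini-mental state examination", "procedure", "SNOMED"),
    cpt(5200, "Urinalysis", "procedure", "SNOMED"),
    cpt(6000, "Laboratory test", "measurement", "LOINC"),
    cpt(6101, "Antinuclear antibody measurement", "measurement", "LOINC"),
    cpt(6102, "Complete blood count", "measurement", "LOINC"),
    # Visits
    cpt(9201, "Inpatient visit", "visit", "Visit"),
    cpt(9202, "Outpatient visit", "visit", "Visit"),
    cpt(9203, "Emergency room visit", "visit", "Visit")
  )
  # Background noise codes: three flat families under a group each.
  noise <- bind_rows(
    cpt(3000, "Common ambulatory condition", "condition", "SNOMED"),
    purrr::map_dfr(1:60, function(i) {
      cpt(3000 + i, sprintf("Background condition %02d", i), "condition", "SNOMED")
    }),
    cpt(4900, "Common medication", "drug", "RxNorm"),
    purrr::map_dfr(1:40, function(i) {
      cpt(4900 + i, sprintf("Background drug %02d", i), "drug", "RxNorm")
    }),
    cpt(5900, "Common procedure", "procedure", "SNOMED"),
    purrr::map_dfr(1:20, function(i) {
      cpt(5900 + i, sprintf("Background procedure %02d", i), "procedure", "SNOMED")
    }),
    cpt(6900, "Common lab panel", "measurement", "LOINC"),
    purrr::map_dfr(1:20, function(i) {
      cpt(6900 + i, sprintf("Background measurement %02d", i), "measurement", "LOINC")
    })
  )
  concepts <- bind_rows(concepts, noise)

  e <- function(parent, child) tibble(parent_id = parent, child_id = child)
  edges <- bind_rows(
    e(1000, 1100), e(1100, c(1101, 1102, 1103, 1104, 1105)),
    e(1200, c(1201, 1202)), e(1210, c(1211, 1212)),
    e(2000, c(2100, 2200, 2300, 2400, 2450)),
    e(2100, c(2101, 2102)), e(2200, 2201), e(2450, c(2451, 2452)),
    e(2500, 2501),
    e(4000, c(4100, 4200, 4300)), e(4100, 4101), e(4200, c(4201, 4202)),
    e(4300, c(4301, 4302)),
    e(4500, c(4510, 4520)), e(4510, c(4511, 4512)), e(4520, 4521),
    e(5000, c(5100, 5200)), e(5100, 5101),
    e(6000, c(6101, 6102)),
    e(3000, 3000 + 1:60), e(4900, 4900 + 1:40),
    e(5900, 5900 + 1:20), e(6900, 6900 + 1:20)
  )
  list(
    concepts = concepts,
    concept_ancestors = ancestor_closure(edges, concepts$concept_id),
    edges = edges
  )
}

#' Designated roll-up groups of the synthetic vocabulary
#'
#' The level-1/2 grouping concepts used when characterization roll-up is
#' requested against the synthetic vocabulary.
#' @return Integer vector of group concept_ids.
#' @export
synthetic_rollup_groups <- function() {
  as.integer(c(1000, 1100, 1200, 1210, 2000, 2100, 2200, 2450, 2500,
               4000, 4100, 4200, 4300, 4500, 4510, 4520,
               5000, 6000, 3000, 4900, 5900, 6900))
}
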