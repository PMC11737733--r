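{
  "schema_version": "1.0",
  "cohort_id": 202,
  "name": "Dementia, restrictive: first Alzheimer diagnosis confirmed by a second diagnosis, competing dementias and recent stroke excluded",
  "concept_sets": [
    {
      "concept_set_id": 1,
      "name": "Alzheimer diagnosis",
      "items": [
        {"concept_id": 2100, "include_descendants": true, "is_excluded": false}
      ]
    },
    {
      "concept_set_id": 2,
      "name": "Anti-dementia drug",
      "items": [
        {"concept_id": 4500, "include_descendants": true, "is_excluded": false}
      ]
    },
    {
      "concept_set_id": 3,
      "name": "Competing dementia diagnoses",
      "items": [
        {"concept_id": 2200, "include_descendants": true, "is_excluded": false},
        {"concept_id": 2300, "include_descendants": false, "is_excluded": false},
        {"concept_id": 2400, "include_descendants": false, "is_excluded": false}
      ]
    },
    {
      "concept_set_id": 4,
      "name": "Stroke",
      "items": [
        {"concept_id": 2500, "include_descendants": true, "is_excluded": false}
      ]
    }
  ],
  "entry_events": [
    {"domain": "condition", "concept_set_id": 1, "occurrence": "first_ever"}
  ],
  "prior_observation_days": 365,
  "inclusion_rules": [
    {
      "name": "A second Alzheimer diagnosis any time after entry",
      "domain": "condition",
      "concept_set_id": 1,
      "window": [1, null],
      "occurrence_count": {"comparator": "at_least", "n": 1}
    },
    {
      "name": "No competing dementia diagnosis at any time",
      "domain": "condition",
      "concept_set_id": 3,
      "window": ["-inf", null],
      "occurrence_count": {"comparator": "at_most", "n": 0}
    },
    {
      "name": "No stroke diagnosis within 2 years before entry",
      "domain": "condition",
      "concept_set_id": 4,
      "window": [-730, -1],
      "occurrence_count": {"comparator": "at_most", "n": 0}
    }
  ],
  "exit": {"strategy": "end_of_observation"}
}
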