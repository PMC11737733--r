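{
  "schema_version": "1.0",
  "cohort_id": 101,
  "name": "Lupus-like: earliest of diagnosis, treatment or symptom, diagnosis required within 90 days",
  "concept_sets": [
    {
      "concept_set_id": 1,
      "name": "Lupus diagnosis",
      "items": [
        {"concept_id": 1100, "include_descendants": true, "is_excluded": false}
      ]
    },
    {
      "concept_set_id": 2,
      "name": "Lupus treatment (illustrative mapping onto the synthetic drug classes)",
      "items": [
        {"concept_id": 4100, "include_descendants": true, "is_excluded": false},
        {"concept_id": 4200, "include_descendants": true, "is_excluded": false},
        {"concept_id": 4300, "include_descendants": true, "is_excluded": false}
      ]
    },
    {
      "concept_set_id": 3,
      "name": "Lupus signs and symptoms",
      "items": [
        {"concept_id": 1200, "include_descendants": true, "is_excluded": false},
        {"concept_id": 1210, "include_descendants": true, "is_excluded": false},
        {"concept_id": 1220, "include_descendants": false, "is_excluded": false}
      ]
    }
  ],
  "entry_events": [
    {"domain": "condition", "concept_set_id": 1, "occurrence": "all"},
    {"domain": "drug", "concept_set_id": 2, "occurrence": "all"},
    {"domain": "condition", "concept_set_id": 3, "occurrence": "all"}
  ],
  "prior_observation_days": 365,
  "inclusion_rules": [
    {
      "name": "At least one lupus diagnosis within 0 to 90 days from entry",
      "domain": "condition",
      "concept_set_id": 1,
      "window": [0, 90],
      "occurrence_count": {"comparator": "at_least", "n": 1}
    }
  ],
  "exit": {"strategy": "end_of_observation"}
}
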