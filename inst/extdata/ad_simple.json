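{
  "schema_version": "1.0",
  "cohort_id": 201,
  "name": "Dementia, simple: first Alzheimer diagnosis",
  "concept_sets": [
    {
      "concept_set_id": 1,
      "name": "Alzheimer diagnosis",
      "items": [
        {"concept_id": 2100, "include_descendants": true, "is_excluded": false}
      ]
    }
  ],
  "entry_events": [
    {"domain": "condition", "concept_set_id": 1, "occurrence": "first_ever"}
  ],
  "prior_observation_days": 365,
  "inclusion_rules": [],
  "exit": {"strategy": "end_of_observation"}
}
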