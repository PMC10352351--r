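{
  "comment": "Worked two-study CITE-seq RNA merge order: three cohorts within each study are corrected first (cohort as the batch label, k_ruv = 10), then the two studies are merged (study as the batch label, k_ruv = 10).",
  "levels": [
    [
      {"name": "studyA", "batch_column": "cohort",
       "members": ["A_cohort1", "A_cohort2", "A_cohort3"], "k_ruv": 10},
      {"name": "studyB", "batch_column": "cohort",
       "members": ["B_cohort1", "B_cohort2", "B_cohort3"], "k_ruv": 10}
    ],
    [
      {"name": "cross-study", "batch_column": "study",
       "members": ["studyA", "studyB"], "k_ruv": 10}
    ]
  ]
}
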