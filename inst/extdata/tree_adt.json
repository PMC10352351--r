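{
  "comment": "Worked two-study CITE-seq ADT merge order: same tree as tree_rna.json but with k_ruv = 3 at both levels, as appropriate for a low-feature antibody panel (HVG selection skipped, all features used as negative controls).",
  "levels": [
    [
      {"name": "studyA", "batch_column": "cohort",
       "members": ["A_cohort1", "A_cohort2", "A_cohort3"], "k_ruv": 3},
      {"name": "studyB", "batch_column": "cohort",
       "members": ["B_cohort1", "B_cohort2", "B_cohort3"], "k_ruv": 3}
    ],
    [
      {"name": "cross-study", "batch_column": "study",
       "members": ["studyA", "studyB"], "k_ruv": 3}
    ]
  ]
}
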