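{
  "name": "toy-stroke",
  "outcome_label": "stroke/TIA",
  "horizon": 10,
  "baseline_survival": 0.9,
  "outcome_fraction": 1.0,
  "predictors": [
    {"name": "age", "transform": "identity", "coefficient": 0.06, "mean": 68},
    {"name": "sbp", "transform": "identity", "coefficient": 0.012, "mean": 150},
    {"name": "smoker", "transform": "indicator", "coefficient": 0.35, "mean": 0.12}
  ],
  "eligibility": [
    {"covariate": "prior_stroke", "exclude_when": true, "label": "Stroke"},
    {"covariate": "prior_tia", "exclude_when": true, "label": "TIA"}
  ]
}
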