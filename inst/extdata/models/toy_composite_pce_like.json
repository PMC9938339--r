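{
  "name": "toy-composite-pce-like",
  "outcome_label": "composite hard CVD (stroke fraction 0.289)",
  "horizon": 10,
  "baseline_survival": 0.85,
  "outcome_fraction": 0.289,
  "clinical_threshold": 0.075,
  "predictors": [
    {"name": "age", "transform": "identity", "coefficient": 0.065, "mean": 68},
    {"name": "sbp", "transform": "log", "coefficient": 1.8, "mean": 5.0106},
    {"name": "smoker", "transform": "indicator", "coefficient": 0.5, "mean": 0.12},
    {"name": "diabetes", "transform": "indicator", "coefficient": 0.55, "mean": 0.09}
  ],
  "eligibility": [
    {"covariate": "prior_stroke", "exclude_when": true, "label": "Stroke"},
    {"covariate": "chd", "exclude_when": true, "label": "Myocardial Infarction/CHD"},
    {"covariate": "af", "exclude_when": true, "label": "Atrial Fibrillation"}
  ]
}
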