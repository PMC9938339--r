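{
  "name": "toy-composite-qrisk-like",
  "outcome_label": "composite CVD (stroke fraction 0.366)",
  "horizon": 10,
  "baseline_survival": 0.78,
  "outcome_fraction": 0.366,
  "clinical_threshold": 0.10,
  "predictors": [
    {"name": "age", "transform": "identity", "coefficient": 0.07, "mean": 68},
    {"name": "chol_hdl_ratio", "transform": "log", "coefficient": 0.9, "mean": 1.4816},
    {"name": "smoker", "transform": "indicator", "coefficient": 0.45, "mean": 0.12},
    {"name": "diabetes", "transform": "indicator", "coefficient": 0.5, "mean": 0.09},
    {"name": "age_x_smoker", "transform": {"type": "product", "terms": ["age", "smoker"]}, "coefficient": -0.004, "mean": 8.16}
  ],
  "eligibility": [
    {"covariate": "prior_stroke", "exclude_when": true, "label": "Stroke"},
    {"covariate": "prior_tia", "exclude_when": true, "label": "TIA"},
    {"covariate": "chd", "exclude_when": true, "label": "Coronary Heart Disease"},
    {"covariate": "statin_use", "exclude_when": true, "label": "Statin use"}
  ]
}
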