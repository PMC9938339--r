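{
  "_comment": "SYNTHETIC template. Populate coefficients, centring means and the published 10y baseline survivor function from the development paper of the tool you are validating; the toy values here are placeholders, not any published model.",
  "name": "my-risk-tool-male",
  "outcome_label": "describe the outcome the tool predicts",
  "horizon": 10,
  "baseline_survival": 0.9,
  "outcome_fraction": 1.0,
  "clinical_threshold": null,
  "predictors": [
    {"name": "age", "transform": "identity", "coefficient": 0.0, "mean": 0.0},
    {"name": "sbp", "transform": "log", "coefficient": 0.0, "mean": 0.0},
    {"name": "smoker", "transform": "indicator", "coefficient": 0.0, "mean": 0.0},
    {"name": "ethnicity", "transform": {"type": "onehot", "level": "south_asian"}, "coefficient": 0.0, "mean": 0.0},
    {"name": "age_x_sbp", "transform": {"type": "product", "terms": ["age", "sbp"]}, "coefficient": 0.0, "mean": 0.0}
  ],
  "eligibility": [
    {"covariate": "prior_stroke", "exclude_when": true, "label": "Stroke"}
  ]
}
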