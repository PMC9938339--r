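# survalid

External validation of proportional-hazards risk prediction models for
time-to-event outcomes under competing risks, in R.

Published cardiovascular risk tools (stroke-specific scores as well as
composite-CVD scores) are Cox-type models shipped as three published
ingredients: predictor coefficients, the development-population centring
means, and the baseline survivor function at the 10-year horizon. `survalid`
takes such a tool as a declarative JSON definition plus a subject-level
cohort table and runs the full external-validation procedure, with every
metric computed twice — the conventional ("main") analysis, and a
competing-risk sensitivity analysis that acknowledges that older adults die
of other causes far more often than they have strokes.

For whom: biostatisticians and epidemiologists validating risk scores in
cohorts with substantial competing mortality, and anyone who needs a
self-contained, testable implementation of the standard validation metrics.

## What it computes

Scoring follows the standard survivor-function formula. With transformed
predictors `t_j(x_j)`, coefficients `b_j` and centring means `m_j`:

    PI  = sum_j b_j * t_j(x_j)          (prognostic index)
    CPI = PI - sum_j b_j * m_j          (centred prognostic index)
    P   = 1 - S0(10) ^ exp(CPI)         (10-year predicted probability)

and composite-tool probabilities are multiplied by a published outcome
fraction (e.g. 0.366, 0.289) before comparison with observed stroke risk.

| Aspect | Main analysis | Competing-risk analysis |
|---|---|---|
| Discrimination | Harrell's C (jackknife SE) | competing deaths recoded event-free |
| Calibration slope | Cox fit of the CPI | event-free recoding at the horizon |
| Mean / decile calibration | Kaplan-Meier observed risk | Aalen-Johansen cause-1 CIF |
| Sn/Sp at a threshold | KM-adjusted cumulative/dynamic | CIF-substituted |

Plus: PI-centile risk groups with per-group KM curves, age-band calibration
(the widening KM−CIF gap with age), clinical-threshold classification for
composite tools (10% / 7.5% applied to unscaled composite probabilities),
threshold sweeps, a minimum-100-events gate, complete-case and eligibility
filtering, multi-model head-to-head comparison on a common sub-sample, and
a synthetic older-cohort generator with cause-specific hazards and a
latent-truth channel that makes every stage testable against known ground
truth.

## Worked example

Generate a synthetic cohort of 4,000 men aged 60–79 and validate it against
its own generating model:

```r
library(survalid)

config <- scenario_config(n = 4000, seed = 1)
cohort <- generate_cohort(config)   # tibble: id, time, event (0/1/2), age, covariates
model  <- scenario_model(config)    # the true net-risk PH model as a risk_model
report <- run_validation(cohort, model)
report
```

```
<survalid_report> model: scenario-true-model  outcome: stroke/TIA within horizon
  n = 4000 (of 4000 loaded), events = 400, competing deaths = 923, horizon = 10y
  [main]
    Harrell's C      0.5959 [0.5696-0.6222]
    Calibration slope 0.76 [0.55-0.97], p vs 1 = 0.02834
    Mean calibration  1.00
    Cut-off 11.67%: Sn 54%, Sp 60% (observed risk 11.7%)
  [competing_risk]
    Harrell's C      0.5846 [0.5584-0.6107]
    Calibration slope 0.64 [0.42-0.85], p vs 1 = 0.0007601
    Mean calibration  1.14
    Cut-off 10.20%: Sn 65%, Sp 48% (observed risk 10.2%)
```

Reading it: 400 of 4,000 men have the stroke outcome within 10 years and
923 die of other causes first. The main-variant mean calibration of 1.00
says the model's average predicted risk matches the KM observed risk — as
it must, since this model generated the data. The competing-risk columns
show the structural effects of competing mortality: the CIF observed risk
(10.2%) sits below the KM estimate (11.7%), so the same predictions now
over-predict on average (ratio 1.14), and discrimination drops slightly.
At a single seed the calibration slope is estimated with events-limited
precision (here 0.76, CI [0.55, 0.97]); the seeded recovery checks in the
test suite show it centres on 1 as it should.

Individual metrics are plain data-frame-in/tibble-out functions
(`harrells_c()`, `calibration_slope()`, `mean_calibration()`,
`decile_calibration()`, `censoring_adjusted_sn_sp()`, ...), results have
`tidy()`/`glance()` methods, and the table-shaped results have `autoplot()`
methods (calibration with a 45° reference, risk-group KM separation,
age-band KM/CIF comparison). A thin CLI lives at `inst/cli/survalid.R`
(`validate`, `head2head`, `simulate` subcommands). Real tools are supplied
as JSON files; `inst/extdata/models/template_model.json` documents the
schema (the shipped model files are synthetic toys — published coefficients
must come from each tool's development paper).

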