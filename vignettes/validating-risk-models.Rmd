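---
title: "Validating proportional-hazards risk models under competing risks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating proportional-hazards risk models under competing risks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survalid)
library(dplyr)
```

## The problem

Published cardiovascular risk scores — stroke-specific tools and
composite-CVD tools alike — are proportional-hazards models summarised by
three published ingredients: predictor coefficients, the means those
predictors were centred at in the development population, and the baseline
survivor function at the prediction horizon. Applying such a tool to a new
cohort and asking "does it still work here?" is *external validation*. In
older cohorts two complications dominate:

* **Competing mortality.** Men in their 60s and 70s die of non-stroke causes
  two to three times as often as they have strokes. The Kaplan-Meier (KM)
  failure estimate treats those deaths as censoring and therefore estimates
  the *net* risk — the risk in a hypothetical world where nothing else can
  happen — which overstates the real-world (crude) probability that a
  stroke occurs. The Aalen-Johansen cumulative incidence function (CIF)
  estimates the crude probability directly.
* **Composite outcomes.** A composite-CVD tool predicts strokes *and*
  coronary events together. To compare its predictions with observed stroke
  risk, the predicted probability is multiplied by the published fraction of
  composite events that are strokes (an *outcome fraction*), while clinical
  decision thresholds remain defined on the unscaled composite scale.

`survalid` implements the full validation procedure around these two
complications, plus a synthetic-cohort generator with known ground truth so
the whole pipeline can be exercised and tested without access to any real
cohort.

## Scoring model

For subject $i$ with transformed predictors $t_j(x_{ij})$, the prognostic
index and centred prognostic index are

$$\mathrm{PI}_i = \sum_j \beta_j t_j(x_{ij}), \qquad
  \mathrm{CPI}_i = \mathrm{PI}_i - \sum_j \beta_j m_j,$$

and the predicted probability of the tool's outcome by the horizon is

$$P_i = 1 - S_0(10)^{\exp(\mathrm{CPI}_i)}.$$

Model definitions are declarative JSON files; the transform vocabulary is
`identity`, natural `log`, binary `indicator`, categorical `onehot` and
`product` (interaction) — enough to express the common published tools. The
engine never imputes: a missing covariate is an error, and
`complete_case_filter()` applies the complete-case rule explicitly (with a
warning above 15% dropped, against the 6–12% typically seen in practice).
Eligibility predicates (history of stroke, statin use, ...) are part of the
model definition and applied by `apply_eligibility()` with per-predicate
exclusion counts.

```{r score-demo}
model <- load_model_definition(
  system.file("extdata", "models", "toy_stroke.json", package = "survalid"))
model
```

## Validation metrics

**Discrimination.** Harrell's C with the standard censoring conventions:
a pair is comparable iff the smaller observed time is an event; tied event
times carry no ordering information; tied predictions count one half. The
standard error is a leave-one-out jackknife assembled in $O(n)$ from
per-subject pair counts (the pair scan itself is compiled code). The
competing-risk variant recodes subjects who die of other causes as known
event-free beyond every observed time before applying the same pair rule.
Risk groups cut at the 16th/50th/84th centiles of the PI (linear-interpolation
quantiles, half-open intervals, top group closed) give the classic KM
separation display.

**Calibration.** The calibration slope is the coefficient of the CPI refit
as the *single* covariate of a Cox model on the validation data; slopes
below 1 mean predictions are too extreme. The fitter maximises the
Breslow-ties partial likelihood by Newton–Raphson (tolerance $10^{-8}$ on
the score, at most 50 iterations, step-halving whenever a step would lower
the likelihood; the covariate is re-centred internally so `exp()` stays
bounded). The Wald interval and the two-sided Wald test of slope = 1 match
the usual reporting convention. Mean calibration is the ratio of mean
predicted (scaled) risk to the observed risk at the horizon — KM for the
main analysis, cause-1 CIF for the competing-risk sensitivity analysis.
Decile calibration ranks subjects by scaled prediction into near-equal bins
(stable input order breaks ties, sizes differ by at most one) and estimates
the observed risk *within* each bin by KM or CIF — not by the raw event
fraction, which would ignore censoring. Age-group calibration repeats this
per age band (default ≤65, >65–≤70, >70–≤75, >75); the KM−CIF gap across
bands displays how strongly competing mortality distorts the naive observed
risk in the oldest groups.

**Classification.** Censoring-adjusted cumulative/dynamic sensitivity and
specificity at a probability threshold $c$: with $q = \Pr(\text{pred} > c)$,
$F$ the overall risk at the horizon and $F^+, F^-$ the risks estimated
within the two sides of the threshold (KM, or CIF under the competing-risk
variant),

$$\mathrm{Sn} = \frac{q\,F^+}{F}, \qquad
  \mathrm{Sp} = \frac{(1-q)(1-F^-)}{1-F}, \qquad
  \mathrm{PPV} = F^+, \qquad \mathrm{NPV} = 1-F^-.$$

Without censoring or competing events these reduce exactly to the classical
2×2-table quantities. Estimates can stray slightly outside $[0,1]$ under
heavy censoring and are clipped (and the clipping reported). Thresholds come
from three sources: the observed risk itself (KM failure, or CIF under
competing risks), conventional clinical thresholds applied to *unscaled*
composite probabilities (10% for QRISK3-type tools, 7.5% for PCE-type
tools) while the outcome classified remains the stroke event, and arbitrary
user sweeps.

On the threshold-scale question for composite tools: thresholds derived from
observed stroke risk are applied to the *scaled* probabilities (the quantity
on the stroke scale), while clinical intervention thresholds are applied to
the *unscaled* composite probabilities, because that is how the thresholds
are defined and used in practice.

## The synthetic cohort generator

`scenario_config()` describes a cohort of men aged 60–79 (truncated normal,
mean 68, sd 5.5) with a reduced risk-factor panel (systolic blood pressure,
cholesterol:HDL ratio, BMI, smoking, diabetes, atrial fibrillation, blood
pressure treatment, plus history flags used only by eligibility predicates).
Stroke and non-stroke death are generated from *cause-specific* exponential
or Weibull hazards: each subject draws a latent time per cause by inverse
transform and the earlier one is observed, alongside independent uniform
dropout (default 4%, matching near-complete follow-up) and administrative
censoring at 10 years. Cause-specific generation was chosen because it makes
the true cause-1 cumulative incidence available in closed form
($\mathrm{CIF}_1(t) = \tfrac{r_1}{r_1+r_2}(1-e^{-(r_1+r_2)t})$ for
exponential hazards; adaptive quadrature for Weibull), giving every
downstream metric an analytic or latent-truth oracle.

The default rates — stroke baseline 0.011/y and non-stroke death 0.026/y at
the covariate means, with a 0.095/y log-hazard age gradient for death —
were chosen so a 4,000-man cohort shows roughly 10% stroke outcomes and
24% competing deaths over 10 years with competing mortality rising steeply
with age, the structure typical of population-based cohorts of older
British men. Because the evaluated model built by `scenario_model()` is the
net-risk proportional-hazards model implied by the stroke hazard
($S_0(10) = e^{-\lambda_{0}\cdot 10}$), validating a cohort against its own
generating model recovers slope ≈ 1 and mean calibration ≈ 1.

Three knobs manufacture the classic failure modes without touching the
evaluated model: `slope_multiplier` (the generating linear predictor is
multiplied by its reciprocal, so the fitted slope attenuates to
$1/\text{multiplier}$), `baseline_inflation` (the generating baseline hazard
is divided by it, so the model globally over-predicts by about that factor)
and `top_tail_inflation` (a hazard multiplier above the 70th centile of the
linear predictor; below 1 it produces over-estimation confined to the top
deciles).

What the generator does **not** emulate: real covariate correlation
structures, informative dropout (a knob exists but defaults off, matching
the usual independent-censoring assumption), measurement error, secular
trends, or haemorrhagic/ischaemic outcome subtypes. Passing tests therefore
demonstrate that the *procedure* is computed correctly under known truth,
not that any particular published tool is well calibrated in any real
population. In the same spirit, the shipped model files are toys: the
package never embeds any published tool's coefficients, and the template
file documents which fields a user must populate from a tool's development
paper.

## A full run

```{r full-run}
config <- scenario_config(n = 4000, seed = 1)
cohort <- generate_cohort(config)
model <- scenario_model(config)
report <- run_validation(cohort, model)
report
```

```{r plots, fig.width = 6, fig.height = 4}
autoplot(decile_calibration(
  bind_cols(cohort[c("time", "event")],
            score_cohort(cohort, model)["scaled_probability"]),
  scaled_probability, time, event))
autoplot(report$risk_group_curves)
autoplot(report$age_table)
```

Several models sharing an outcome can be compared on one common sub-sample
(union of all eligibility exclusions, union of complete-case requirements)
with `run_head_to_head()`, which also bins subjects by deciles of the
across-model mean prediction to show where the tools agree and where they
diverge.

## Numerical and design choices

* **Ties.** Breslow approximation in the Cox fitter (parity with the most
  common software default); censoring processed after events at tied times
  in all curves; event/censored ties in the C-index compared with the event
  treated as earlier, event/event ties not comparable.
* **Quantiles.** Linear interpolation between order statistics (R type 7)
  for PI centiles — pinned for reproducibility.
* **Degenerate inputs.** A constant covariate, zero comparable pairs, zero
  observed risk, or an empty threshold side raise explicit errors or flagged
  degenerate results, never silent numbers. An overflowing
  $\exp(\mathrm{CPI})$ saturates the predicted probability just below 1 with
  a warning, since it almost always signals a scoring bug.
* **Competing-risk slope.** The competing-risk variant of the calibration
  slope recodes competing deaths as event-free at the horizon (the same
  recoding as the concordance adaptation) rather than fitting a
  subdistribution regression, which is out of scope.
* **Determinism.** Bin assignment uses stable sorts, generation is
  bit-reproducible given `(config, seed)`, and reports contain no
  timestamps, so identical runs write byte-identical output.
* **Problem sizes.** The shipped checks validate slope recovery at
  $n = 10{,}000$ (on a dedicated single-marker scenario with ~40% ten-year
  events, sized so the slope standard error ≈ 0.02 makes a ±0.05 recovery
  band a meaningful ~3σ check — the default cohort's narrow risk spread
  would leave that band dominated by noise), classification and mean
  calibration at $n = 20{,}000$, and the age-band mechanism at
  $n = 40{,}000$; oracle equivalences run at enumerable sizes
  ($n \le 300$).
* **Estimand caveats.** The KM reference estimates net risk; when competing
  deaths share risk factors with the outcome, KM is mildly biased for the
  net-risk estimand because the competing censoring is then informative.
  The known-truth recovery checks for KM-referenced quantities therefore use
  scenarios without competing deaths; competing-risk behaviour is checked
  against its own CIF-based estimands and directional properties (CIF ≤ KM
  risk, CR ratio ≥ main ratio, the widening age-band gap).

## Limitations

Only male-equation-style single-model definitions are supported (no
re-derivation or audit of published coefficients, no female equations in the
shipped toys); multi-covariate Cox regression, Fine–Gray subdistribution
models, Greenwood variances for the curves, time-dependent ROC/AUC and
recalibration are deliberately out of scope. The jackknife SE for the
C-index is exact but $O(n)$ after the $O(n^2)$ pair scan, so very large
cohorts pay a quadratic cost in the pair enumeration.
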