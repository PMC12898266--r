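---
title: "Summarizing longitudinal clinical measurements for mortality risk models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Summarizing longitudinal clinical measurements for mortality risk models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longlabs)
```

## The problem

Prediction models in clinical epidemiology usually reduce a patient's vital
signs and laboratory history to the most recent value of each analyte, or
ignore it altogether in favour of diagnosis-based comorbidity indices. Yet a
clinician reading a chart weighs the whole value set: how long and how often
a measurement has been off target, how much cumulative exposure the excess
represents, whether the current abnormality is an entrenched run or a fresh
relapse, how labile the series is, and which way it is trending.

`longlabs` operationalizes that reading. For each of 11 routinely collected
clinical measurements (CMs) — SBP, DBP, O2Sat, BMI, eGFR, serum albumin,
HCT, ALT, A1c, HDL and LDL — it condenses a patient's complete longitudinal
record into 13 parameters organized by 7 clinical attributes, and feeds the
resulting 13 × 11 = 143 candidate predictors into a logistic modelling
pipeline for 60-day mortality after an index event: per-CM subset models, an
attribute-set-wise stepwise main model, a per-patient predicted probability
of death (PDeathLabs), and AUROC comparisons against age and
comorbidity-score baselines.

## The parameters

All parameters are read from a *running summary* that is updated whenever a
new value arrives, so a patient's status is available at any point in time;
a batch implementation recomputes the same quantities from the full series
and serves as the reference. Only readings up to 14 days before the index
date are used (a configurable blackout that excludes measurements possibly
taken during the pre-symptomatic phase of the index illness).

Abnormality is defined against a per-CM treatment target (`low`/`high`
bounds; strict inequalities, so a value exactly at the bound is normal).
Targets are user-supplied configuration; the shipped defaults are
conventional adult outpatient thresholds and are documented, not clinical
advice. Note the albumin default assumes *serum* albumin in g/dL; a source
recording urinary albumin needs a different target and direction.

| Attribute | Parameter | Definition |
|---|---|---|
| Current control | `Value1` | most recent value |
| Chronicity | `FUDaysNotAtGoal` | days spanned by abnormal→abnormal reading pairs |
| | `NumNotAtGoal` | number of abnormal readings |
| Disease burden | `AbnAUC` | trapezoidal area of the excess outside the target (unit·days) |
| | `TimeWtAvg` | trapezoidal AUC / days of follow-up (CM units) |
| Refractoriness | `TimeNotAtGoal` | duration of the open abnormal run (days) |
| | `CtNotAtGoal` | reading count of the open abnormal run |
| | `MaxClustDays` | longest duration among runs of ≥ 2 abnormal readings |
| Relapse | `NumClust` | number of abnormal clusters |
| Lability | `CoeffVar` | sample SD / mean of all values |
| | `MeanValDiff` | mean absolute consecutive difference |
| Trends | `NetChange` | most recent minus first value |
| | `Lag3Dev` | (Value1 − mean of 3 preceding values) / that mean |

Successive reading pairs are classified four ways — at goal, not at goal,
worsening, improving — by the abnormality of their endpoints.
`FUDaysNotAtGoal` sums only the not-at-goal (abnormal→abnormal) spans;
worsening and improving intervals belong to neither total, since the rule
assigns them their own labels.

A *cluster* is a maximal run of consecutive abnormal readings: it opens on a
normal→abnormal transition (or an abnormal first reading — patients can
enter care already off target) and closes at the next normal reading. An
unterminated run is an *open* cluster; it counts toward `NumClust`, and its
duration and count are exactly the refractoriness of the current state.
Cluster duration runs from the first to the last abnormal reading of the
run; the day of the closing normal reading is not included, because the
improving interval is classified separately.

### Missingness semantics

Missingness is meaningful, not incidental:

* `TimeNotAtGoal`/`CtNotAtGoal` exist only for patients whose most recent
  reading is abnormal (otherwise there is no open run to describe).
* `MaxClustDays` requires at least one cluster of ≥ 2 consecutive abnormal
  readings.
* `AbnAUC`, `TimeWtAvg`, `CoeffVar`, `MeanValDiff` need ≥ 2 readings;
  `Lag3Dev` needs 3 lagging values (≥ 4 readings) and a nonzero lagging
  mean; `CoeffVar` needs a nonzero mean.
* `NetChange` is 0 for a single reading (most recent = first); with no
  readings at all, the whole vector is missing.

One boundary case deserves a note: for a single reading we set
`FUDaysNotAtGoal = 0` and let `NumNotAtGoal` count that reading, because
both are sums over (an empty set of) pairs and readings — this keeps the
chronicity operation total, while area- and dispersion-based parameters are
missing at n = 1 by their own preconditions.

Downstream models use case-wise deletion, so these rules focus the fitted
cohort on patients abnormal at the index with at least one sustained
abnormal episode — a deliberate property of the design, mirrored by the
synthetic cohort defaults below.

### Numerical choices

* All computation is in whole days (date resolution). Same-day duplicate
  readings keep the last entered value, with a warning, so spans are always
  well defined.
* AUC and AbnAUC use endpoint trapezoids only — no interpolation,
  extrapolation or curve fitting, and no computed threshold crossings. A
  segment crossing the bound therefore contributes a half-triangle based on
  endpoint excesses; this is documented behaviour, not an approximation to
  be "fixed".
* `TimeWtAvg` divides the full AUC by follow-up days, which makes it the
  time-weighted mean of the CM (bounded by the observed minimum and
  maximum). The alternative reading (excess area over follow-up) is
  available as `mode = "abnormal"` in the deriving functions.
* `CoeffVar` uses the sample (n−1) standard deviation, the convention in
  the visit-to-visit variability literature.
* `Lag3Dev` requires exactly 3 lagging values; it is never computed on a
  shorter window.
* Accumulators are plain doubles; the incremental and batch paths apply
  the same operations in the same order and are required (and tested on
  1000 random series) to agree exactly on counts/days and to 1e-9 relative
  on reals. A single-pass C++ core computes the same quantities for whole
  cohorts and is cross-checked elementwise against both R paths.

### Why the time-weighted average matters

Clinicians remeasure what worries them, so abnormal phases are sampled more
densely and the raw mean of the readings is biased toward the abnormal
side. The trapezoidal time weighting removes exactly this artefact: adding
a reading that lies on the line segment between two existing readings (a
denser sampling of the same trajectory) leaves the AUC — and hence
`TimeWtAvg` — unchanged, while the raw mean moves. The test suite asserts
this invariance at 1e-9 relative tolerance on generator output.

## The synthetic cohort generator

The data the method was designed for (a national EHR research warehouse)
cannot ship with a package, so `simulate_cohort()` generates cohorts with
the longitudinal structure the method assumes, and the whole pipeline is
exercised end to end on them.

Per patient and CM, a latent trajectory = patient baseline + linear drift
(per year, toward the abnormal side) + transient relapse excursions (a
Poisson process of episodes with random magnitude and exponentially
distributed duration); readings add Gaussian noise. Visits are an
inhomogeneous Poisson process thinned from a constant-rate candidate
stream: 1.5 visits/year while the latent value is at goal, multiplied by
2.5 while abnormal — emulating abnormality-driven oversampling. Follow-up
is uniform on 4–10 years; series end 14 days before the index date by
construction. Each CM's series is absent entirely with probability 0.02,
independently.

The default trajectory parameters describe a high-burden chronic-disease
cohort in which most series drift beyond target during follow-up. That is
deliberate: the refractoriness parameters are observed only for patients
abnormal at their most recent reading, so a cohort must be substantially
abnormal for the 143-column complete-case analysis to retain a meaningful
fraction of patients (roughly 30% under the defaults, with a marginal
60-day death rate near 13% — an enriched, high-acuity cohort).

The 60-day outcome is drawn from a logistic model applied to the *true
derived parameters* — the engine's own output on the generated series — so
recovery tests are well posed against the engine's definitions rather than
against unobservable latent states. Six parameters spanning six attributes
carry signal by default (`O2SatValue1` −, `SBPTimeWtAvg` +, `A1cNumClust`
+, `eGFRNetChange` −, `HCTCoeffVar` +, `AlbFUDaysNotAtGoal` +), applied on
standardized scales whose centers and scales are fixed scenario constants
(calibrated once against the generator defaults and then frozen), so the
implied raw-scale coefficients are known exactly
(`true_raw_coefficients()`). Patients missing a signal parameter contribute
its centered mean (z = 0) to their linear predictor. Comorbidity scores are
Poisson draws whose rate increases with the patient's true metabolic
burden, giving the baseline comparator models realistic but
non-outcome-defining signal; age is drawn independently and carries no
effect by default (the coefficients exist in the scenario for users who
want an age-driven cohort).

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: assay changes and unit drift, informative
missingness (absence correlated with health state), measurement error that
depends on the value, competing risks, care-pattern changes at diagnosis
boundaries, and the marginal distributions of any particular health system.
The generator validates the machinery, not the clinical conclusions.

Determinism: one seed drives a fixed vectorized draw order, so a cohort is
byte-identical across runs of the same version; tests assert this.

## The modelling pipeline

`build_design_matrix()` truncates at index − 14 days, derives parameters per
patient × CM, and lays them out CM-major as `<CM><Parameter>` columns next
to the outcome and covariates. Missing parameters propagate as missing
cells; a patient without a CM has all 13 of its cells missing.

*Subset models.* For each CM, `subset_regression()` fits death on that CM's
13 parameters by maximum likelihood after case-wise deletion and reports
the in-sample AUROC of the fitted probabilities. Non-convergence and
separation are reported (`converged = FALSE`), never silently ignored.

*Stepwise main model.* Case-wise deletion over all 143 candidates is
applied once, up front — the model is developed on patients with complete
data. Modelling starts with the most-recent-value set and adds the
attribute sets in a configurable order (default: control, chronicity,
burden, refractoriness, relapse, lability, trends). After each set enters,
terms are removed one at a time — worst Wald p first, refitting after every
drop — until all retained terms have p < 0.05; terms that entered earlier
may be removed at any later stage. Two interpretation choices are
deliberate and configurable: "adjusted p-value" is read as the
covariate-adjusted Wald p from the multivariable fit (no multiplicity
correction — the reporting convention of the underlying tables), and each
attribute set enters whole before pruning (rather than forward-selecting
within the set). Aliased (collinear) columns are dropped with a log entry.
Evaluation is in-sample, matching a development-only design.

`predict_pdeathlabs()` applies the inverse logistic link to the final
model's linear predictor. `compute_auroc()` is the Mann–Whitney
concordance (ties one half) with a DeLong standard error;
`compare_auroc()` is the two-sided DeLong test, paired by default. The
"±" values reported throughout are DeLong standard errors and are labelled
as such. `single_factor_model()` provides the age and comorbidity-score
baselines; since a one-predictor logistic probability is a monotone
transform of the covariate, its AUROC equals the raw covariate's.

A note on null behaviour: an in-sample AUROC of a freshly fitted
13-parameter model is optimistically biased above 0.5 even when the outcome
is pure noise (≈ 0.53–0.54 at ~1000 events under the null scenario). The
test suite therefore checks absence of true discrimination by scoring
null-fitted subset models on an independent null cohort, where the AUROC is
within Monte-Carlo error of 0.5; in-sample reporting stays as designed.

## Problem sizes and tolerances in the test suite

The acceptance tests run the recovery and null experiments at n = 20,000
patients × 20 replicates each (the scale at which stepwise retention and
±2 SE coefficient coverage are stable claims), the incremental/batch
contract on 1000 random series at 1e-9 relative tolerance, the
sampling-density invariance on 100 generator series, and the AUROC
machinery against an O(n²) concordance oracle on fixtures up to 200
patients plus a 200-replicate type-I experiment for the paired DeLong test.
The acceptance script (`scripts/acceptance.R`) reruns the full pipeline on
a 20,000-patient cohort.

## Known limitations

* Day resolution only; multiple same-day readings collapse to the last.
* The stepwise procedure inherits the usual caveats of stepwise inference
  (inflated per-term error, post-selection p-values); the null-scenario
  test brackets the retention rate (1–12% per candidate at α = 0.05) but
  the fitted p-values are not corrected for selection.
* In-sample AUROCs are optimistic; no bootstrap-optimism correction is
  applied by default.
* Case-wise deletion means the fitted population is conditioned on being
  abnormal at the index for every CM in the model — a design property to
  keep in mind when interpreting coefficients.
* BMI derivation forward-fills the most recent prior height; weights
  before any height are dropped.
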