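# longlabs

Most clinical prediction models reduce a patient's vital signs and
laboratory history to a single recent value per analyte, or skip it in
favour of diagnosis-count comorbidity indices. `longlabs` instead condenses
the *complete* longitudinal record of 11 routinely collected clinical
measurements (CMs) — SBP, DBP, O2Sat, BMI, eGFR, serum albumin, HCT, ALT,
A1c, HDL, LDL — into 13 parameters per CM spanning 7 clinical attributes,
and builds a mortality prediction pipeline on the resulting 13 × 11 = 143
candidate predictors. It is written for biostatisticians and clinical
informaticians who need longitudinal EHR feature derivation plus the
downstream modelling in one reproducible tool.

For a series of readings v₁…vₙ at days d₁…dₙ with a treatment target
(abnormal = strictly below `low` or above `high`):

* **Current control** — `Value1` = vₙ.
* **Chronicity** — `FUDaysNotAtGoal` = Σ (dᵢ₊₁ − dᵢ) over abnormal→abnormal
  pairs; `NumNotAtGoal` = #{vᵢ abnormal}. Worsening (normal→abnormal) and
  improving (abnormal→normal) intervals count toward neither total.
* **Disease burden** — trapezoidal `AUC` = Σ (vᵢ + vᵢ₊₁)/2 · (dᵢ₊₁ − dᵢ)
  without interpolation or curve fitting; `AbnAUC` integrates the excess
  e(v) = max(v − high, 0) + max(low − v, 0); `TimeWtAvg` = AUC/(dₙ − d₁),
  immune to the oversampling of abnormal phases that biases the raw mean.
* **Refractoriness / relapse** — maximal runs of consecutive abnormal
  readings ("clusters", opened by a normal→abnormal transition or an
  abnormal first reading, closed by the next normal value): `TimeNotAtGoal`
  and `CtNotAtGoal` describe the open run (missing when the last reading is
  normal), `MaxClustDays` the longest run with ≥ 2 readings, `NumClust` the
  run count.
* **Lability** — `CoeffVar` = sample SD/mean; `MeanValDiff` =
  Σ|vᵢ₊₁ − vᵢ|/(n − 1).
* **Trends** — `NetChange` = vₙ − v₁; `Lag3Dev` = (vₙ − Lag3Mean)/Lag3Mean
  with Lag3Mean the mean of the 3 preceding values.

Only readings up to 14 days before the index date enter (configurable
blackout). The pipeline then fits per-CM subset logistic models, a stepwise
main model with attribute-set-wise entry (starting from the most recent
values) and one-at-a-time backward removal at Wald p ≥ 0.05, assigns each
patient a predicted death probability (**PDeathLabs**), and compares AUROCs
(Mann–Whitney concordance, DeLong standard errors and tests) against age
and Charlson/Elixhauser baselines. A synthetic EHR cohort generator with
irregular, abnormality-intensified visit times makes the whole pipeline
testable end to end without access to clinical data.

## Worked example

```r
library(longlabs)

s  <- cm_series("P1", "SBP", day = c(0, 10, 20, 30),
                value = c(130, 150, 160, 135))
tg <- target_spec("SBP", high = 140)
batch_derive(s, tg)
#> <cm_parameters>
#>          Value1 FUDaysNotAtGoal    NumNotAtGoal          AbnAUC       TimeWtAvg
#>    135.00000000     10.00000000      2.00000000    300.00000000    147.50000000
#>   TimeNotAtGoal     CtNotAtGoal    MaxClustDays        NumClust        CoeffVar
#>              NA              NA     10.00000000      1.00000000      0.09578384
#>     MeanValDiff       NetChange         Lag3Dev
#>     18.33333333      5.00000000     -0.07954545
```

Reading it like a clinician: the latest SBP (135) is back at goal, but the
patient spent 10 of 30 days not at goal across 2 abnormal readings forming
one 10-day, 2-reading cluster; the excess burden above the 140 mmHg target
was 300 mmHg·days; the time-weighted mean (147.5) sits above the target
even though the raw visit mean is pulled further up by the densely sampled
abnormal stretch; the series is modestly labile (CV 9.6%) and ends 8%
below the mean of the three preceding readings. `TimeNotAtGoal` and
`CtNotAtGoal` are missing because the current state is not abnormal.

The same engine runs incrementally (`new_running_summary()`,
`update_summary()`, `finalize_summary()`) and at cohort scale
(`derive_parameter_table()`, `build_design_matrix()`). A full synthetic
study:

```r
cohort <- simulate_cohort(4000, default_scenario(), seed = 1)
dm  <- build_design_matrix(cohort)                  # 143 candidates
fit <- stepwise_main_model(dm)                      # set-wise stepwise
cc  <- casewise_complete(dm, c(candidate_columns(dm), "death60"))
roc <- compute_auroc(predict_pdeathlabs(fit, cc), cc$death60)
roc
#> <ll_roc> AUROC 0.8294 +/- 0.0145 (DeLong), 245 cases / 862 controls
```

There is also a command-line front end (`inst/scripts/longlabs`) with
`derive`, `simulate`, `fit` and `report` subcommands over CSV/YAML/TSV/JSON
artifacts; see `?cli_main`.

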