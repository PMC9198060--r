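# bloodgas

Continuous noninvasive estimation of blood gas pH and arterial CO₂
tension (PaCO₂) for mechanically ventilated patients.

Ventilated patients — especially children — need frequent invasive blood
draws to monitor acid–base status and adjust the ventilator. Between
draws, bedside monitors already stream closely related signals: end-tidal
CO₂ (PetCO₂) from capnography, SpO₂, FiO₂ and ventilator pressures. This
package estimates the *current* blood gas from those noninvasive signals
plus the most recent invasive blood gas, and — crucially for clinical
use — knows when not to guess: predictions with high ensemble uncertainty
are abstained on, so a fresh blood draw can be requested instead.

It is aimed at researchers in clinical prediction modelling and
respiratory physiology who want a transparent, fully testable
implementation of selective blood-gas estimation, including a synthetic
ventilated-cohort simulator so everything runs without access to
protected clinical data.

## The model

The core is a *key-predictor pairwise regression*. One predictor — the
previous pH, written `z` — modulates the linear effect of every other
predictor `x_i` through a bank of `M` sigmoid basis functions `f_j`:

```
ŷ = Σ_{j=1..M} Σ_{i=1..K} w_{i,j} · f_j(z) · x_i
```

with `f_j(z) = 1 / (1 + exp(−slope · (z − c_j)))`, centers `c_1 < … <
c_M` placed at quantiles of the training previous-pH values and, by
default, normalized across the bank to a partition of unity. The `x_i`
are the standardized noninvasive predictors (previous PaCO₂ and HCO₃⁻,
current and previous etCO₂, and current-minus-previous deltas of FiO₂,
PEEP, PIP, mean airway pressure, SpO₂ and tidal volumes) plus a constant
term through which the key predictor's own effect enters. Weights are
fitted by closed-form ridge regression with inner-cross-validation
selection of `(M, slope, λ)`.

Because the model is bilinear, each prediction decomposes *exactly* into
additive per-predictor contributions `g(x_i)`. That powers:

* **Importance ranking** — `I_i = g(x_i) − g(x̄_i)`, the change in
  contribution relative to the population mean, shown for the top
  predictors of each estimate;
* **Pairwise visualization** — the learned contribution surface over
  (previous pH, predictor) grids;
* **Uncertainty and abstention** — replicate models, one per outer
  cross-validation fold, are trained alongside the final model; the
  variance of their predictions is the prediction uncertainty, and a
  calibrated threshold (fixed abstention rate, or the pre-defined
  criterion "retained 95th-percentile |pH error| ≤ 0.1 while abstaining
  on at most half of patients") decides when to abstain.

Physiologic baselines (dead-space carry-forward via
Henderson–Hasselbalch, and a capnography-free linear regression) and an
evaluation suite (95th-percentile errors overall, per pH/PCO₂ range and
per time-lag bin, CLIA ±0.04 pH / ±5 mmHg agreement, Bland–Altman
limits, risk–coverage curves, Mann–Whitney model comparison) round out
the package.

## Worked example

```r
library(bloodgas)

# a synthetic 300-patient ventilated cohort
cohort <- simulate_cohort(bg_generator_config(n_patients = 300, seed = 1))
cohort_realism_report(cohort)
#> Cohort: 1829 observations, 300 patients
#>                median    q25    q75
#> ph              7.393  7.346  7.442
#> paco2          44.746 38.863 50.072
#> petco2         39.537 34.037 45.094
#> avdsf           0.111  0.063  0.158
#> inter_bg_hours  4.362  3.016  6.638
#> pH fractions: 13.4% < 7.3, 64.0% 7.3-7.45, 22.6% >= 7.45

rows  <- build_feature_rows(plausibility_filter(cohort)$cohort)
plan  <- make_split_plan(rows, seed = 1)
train <- resample_by_ph(rows, seed = 1)     # derivation data only

ens <- bg_ensemble(train, plan, target = "ph", lambda = 1)
ens <- calibrate_threshold(ens, rows, criterion = "rate", rate = 0.25)
ens
#> Blood-gas ensemble predictor (target: ph, 5 outer-fold replicates)
#>   threshold: 2.737e-06 (rate criterion, 25.0% abstained at calibration)

newrows <- build_feature_rows(
  simulate_cohort(bg_generator_config(n_patients = 100, seed = 2)))
pred <- predict_or_abstain(ens, newrows)
head(pred[, c("point", "uncertainty", "abstained", "top1")], 4)
#>   point uncertainty abstained       top1
#> 1  7.39    8.13e-07     FALSE    etco2_t
#> 2  7.42    4.50e-07     FALSE    etco2_t
#> 3  7.42    3.21e-07     FALSE    etco2_t
#> 4  7.37    1.95e-06     FALSE etco2_prev
```

Each row gives the final-model point estimate (pH units), the variance
of the five fold-model predictions (pH²), the abstention decision, and
the most influential predictor for that estimate. Per-sample importance
is available in full:

```r
rank_importance(ens$final_model, newrows[1, ])[1:3, ]
#>    predictor importance value population_mean
#> 1    etco2_t     -0.055    46              40
#> 2 etco2_prev      0.039    46              40
#> 3  hco3_prev      0.014    29              26
```

This patient's end-tidal CO₂ of 46 mmHg sits above the population mean
of 40, pulling the pH estimate down by 0.055 units. On the non-abstained
estimates of this held-out cohort:

```r
err <- pred$point[!pred$abstained] - newrows$ph_t[!pred$abstained]
p95_abs_error(err)          # 0.0447 pH units
clia_agreement(err, 0.04)   # 0.913
```

i.e. all but the worst 5% of estimates are within ±0.045 pH units of
the laboratory value, and 91% are within the CLIA blood-gas-analyzer
equivalence bound.

`run_pipeline(bg_pipeline_config(), out_dir)` executes the whole chain —
simulate, filter, feature-build, resample, split, select
hyperparameters, train, calibrate, predict-or-abstain, evaluate — and
writes cohorts, models (JSON), predictions (CSV), the evaluation report
(JSON) and optional figures. A thin command-line wrapper lives in
`inst/scripts/bg_pipeline.R`.

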