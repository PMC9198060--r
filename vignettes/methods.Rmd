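---
title: "Selective blood-gas estimation: model, uncertainty, and synthetic benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selective blood-gas estimation: model, uncertainty, and synthetic benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bloodgas)
```

## The estimation problem

A ventilated patient's acid–base state is summarized by the blood gas:
pH, arterial CO₂ tension (PaCO₂, mmHg) and bicarbonate (HCO₃⁻, mmol/L),
linked by the Henderson–Hasselbalch relation

$$\mathrm{pH} = 6.1 + \log_{10}\!\frac{[\mathrm{HCO_3^-}]}{0.03\,\mathrm{PaCO_2}},$$

with the standard apparent pK 6.1 and CO₂ solubility 0.03 mmol/L/mmHg.
Blood gases require invasive draws; between draws, capnography (end-tidal
CO₂), pulse oximetry and ventilator settings are continuously available.
The package estimates the current pH and PaCO₂ from those noninvasive
signals plus the most recent blood gas, and abstains when its own
uncertainty is too high.

## The pairwise model

For target $y$ (current pH or PaCO₂), key predictor $z$ (previous pH)
and non-key predictors $x_1,\dots,x_K$,

$$\hat y = \sum_{j=1}^{M}\sum_{i=1}^{K} w_{i,j}\, f_j(z)\, x_i .$$

Assumptions worth stating explicitly:

* **The previous blood gas is informative and decays with age.** The
  feature builder links each observation to the most recent prior blood
  gas within 24 h; anything older is discarded.
* **Physiology differs by pH regime but effects are locally linear.**
  Conditional on $z$, every predictor acts linearly; the sigmoid bank
  lets those linear effects change smoothly across pH regimes
  (acidotic / normal / alkalotic).
* **Monotone marginal effects.** For fixed $z$ the contribution of
  $x_i$ is exactly linear with slope $\sum_j w_{i,j} f_j(z)$, so learned
  relationships are interpretable and sign-checkable (a higher current
  end-tidal CO₂ must lower the estimated pH).

### Basis: normalized sigmoids at data quantiles

Two genuinely open design points were resolved as follows.

*Normalization.* With raw logistic bases the design spans no constant:
the constant non-key term $x_0 = 1$ only produces columns
$f_j(z)$, and representing a simple intercept requires near-cancelling
weights across heavily collinear columns. In development this was not a
cosmetic concern — on wider-pH cohorts the raw-basis fit was worse than
a plain linear model and weight magnitudes exploded. The package
therefore defaults to the partition-of-unity variant
$\tilde f_j(z) = f_j(z) / \sum_k f_k(z)$: the bank sums to one, spans
constants, conditions well, and each $w_{i,j}$ reads as "effect of
$x_i$ in the pH regime around center $c_j$". The raw basis remains
available (`sigmoid_basis(..., normalize = FALSE)`) and is what the
monotonicity properties are tested on.

*Center placement.* Centers sit at the $M$ equally spaced quantiles
(probabilities $k/(M+1)$) of the *training* key values rather than on a
fixed pH grid. Fixed-range centers saturate outside their span, so a
cohort whose pH distribution is wider than the chosen grid cannot be
tracked at its tails; quantile placement follows the data by
construction.

### Fitting and hyperparameters

Weights minimize $\lVert y - Xw\rVert^2 + \lambda\lVert w_{\text{pen}}
\rVert^2$ in closed form (QR on the $\sqrt\lambda$-augmented system);
constant-term columns are unpenalized. Non-key predictors are
standardized with training centers/scales (stored in the model); targets
stay on their natural scale. Tunables and defaults:

| parameter | default | grid | rationale |
|---|---|---|---|
| $M$ (centers) | 5 | {3, 5, 7} | few regimes suffice; more overfits small bins |
| slope | 10 /pH unit | {5, 10, 20} | transition widths 0.05–0.2 pH, the scale of the clinical ranges |
| $\lambda$ | 1 | $10^{-3}\dots10^{3}$ | standardized design makes a unit penalty a sensible center |

Selection minimizes the mean inner-fold 95th-percentile absolute pH
error over a 5-inner-fold split (standardization recomputed per
training split); ties keep the earlier grid point, so selection is
deterministic given the split plan.

### Decomposition and importance

Bilinearity gives an exact additive decomposition
$\hat y = \sum_{i=0}^{K} g(x_i)$ with
$g(x_i) = \bigl(\sum_j w_{i,j} f_j(z)\bigr) x_i$ (the $i=0$ term is the
constant block, i.e. the key predictor's own effect). Importance is the
contribution shift relative to the population mean stored at training
time, $I_i = g(x_i) - g(\bar x_i)$, evaluated with the key at its
*observed* value — the alternative (key at its mean) would conflate a
predictor's own deviation with the patient's pH regime. Rankings sort
by $|I_i|$ with ties broken by the fixed predictor order.

## Uncertainty and abstention

Five replicate models — one per outer cross-validation fold, each
trained on the other folds' patients — accompany the final model
trained on all derivation data. Prediction uncertainty is the
*population* variance (denominator = number of replicates) of the
replicate predictions; the displayed interval is the point estimate
±1.96 standard deviations of that spread. A patient-level bootstrap
(`method = "bootstrap"`) is available as an alternative replicate
source.

Abstention applies a strict threshold: abstain iff variance >
threshold, so a degenerate all-equal uncertainty distribution abstains
nothing. Two calibration criteria:

* **rate** (default 0.25): threshold at the 75th percentile
  (type-7 quantile) of calibration uncertainties, i.e. abstain the most
  uncertain quarter;
* **error_bound**: the smallest abstention rate whose retained
  95th-percentile |pH error| is ≤ 0.1 pH units, subject to abstaining
  on at most half of patients (a patient counts as abstained-on when
  any of its samples is). The scan walks thresholds from most to least
  permissive, so it terminates at the minimal abstention satisfying the
  bound; an unsatisfiable bound raises an error that reports the best
  achievable retained error.

Calibration uses derivation data and is then frozen; the pH-calibrated
abstention decision is shared with the paired PaCO₂ estimate, since
abstention is a property of the estimation as a whole. When the
unabstained error already meets the bound, the error-bound criterion
correctly abstains nothing.

## The synthetic cohort simulator

No clinical dataset ships with the package; the simulator generates
cohorts with the statistical structure the model assumes, so every
property is testable end-to-end.

Per patient: PaCO₂ follows a mean-reverting AR(1) around an equilibrium
that ventilator interventions shift (raising pressure lowers the CO₂
equilibrium at `intervention_effect_mmHg_per_cmH2O`, default 0.8);
HCO₃⁻ follows a slow random walk (the metabolic component,
`metabolic_drift_sd` 0.5 mmol/L per median step); pH is *computed*
from the two via Henderson–Hasselbalch, so generated triples are
consistent by construction; PetCO₂ is PaCO₂ reduced by a per-patient
alveolar dead-space fraction (drawn 0.11 ± 0.06, truncated to [0, 0.6])
plus capnograph noise. Sampling gaps are lognormal with median 4.5 h
and sdlog 0.6; irregular gaps scale both the AR coefficient
(`0.85^(dt/median)`) and innovation SDs (`sqrt(dt/median)`), so serial
correlation decays and noise accumulates with elapsed time. About 29%
of patients are seeded outside 7.3–7.45 (38% of those acidotic), 10% of
samples are capillary, and a per-patient lognormal noise multiplier
(sdlog 0.4) encodes differing physiologic stability — the
heteroscedasticity that makes ensemble uncertainty informative. SpO₂ is
a bounded monotone map of FiO₂ with noise; it exists so the ΔSpO₂/ΔFiO₂
predictors carry signal, not as an oxygenation model.

What the simulator does *not* emulate: disease-specific trajectories,
oxygenation indices, missingness patterns, charting artifacts,
inter-center differences, or the true joint distribution of ventilator
management decisions. Passing tests therefore demonstrate that the
machinery behaves as designed under the stated generative assumptions —
not that clinical-data accuracy figures would be reproduced.

Two named benchmark regimes are used by the test suite:

* **heteroscedastic** (the defaults): used for risk–coverage
  dominance — per-patient noise multipliers create rows whose errors
  and ensemble variances co-vary;
* **drifting** (`metabolic_drift_sd = 1.0`, `noise_heterogeneity = 0`):
  used for the time-lag and first-vs-previous-blood-gas properties.
  Bicarbonate drift is the one error channel the model cannot correct
  from the current end-tidal CO₂, so it carries the lag signal; noise
  homogeneity matters because per-bin 95th percentiles in sparse lag
  bins are dominated by the noisiest patients otherwise. An earlier
  stronger-drift variant (2.0) pushed bicarbonate against its
  physiologic clamp and widened the pH range enough that basis
  saturation, not lag, dominated errors — a useful reminder that tail
  percentiles are fragile diagnostics.

## Data processing rules

* **Plausibility filter**: generous physiologic bounds (pH 6.5–7.8,
  PaCO₂ 10–150 mmHg, PetCO₂ 0–150, SpO₂ 0–100%, FiO₂ 21–100%, PEEP
  0–25, PIP 0–60, MnAwP 0–45 cmH₂O, tidal volumes 0–25 mL/kg);
  violations are dropped and logged. `NA` is not a violation.
* **pH rebalancing** (derivation only, never validation): rows are
  subsampled/duplicated per pH bin (<7.3 / 7.3–7.45 / ≥7.45) toward
  target masses 0.17/0.54/0.29, with per-row multiplicities recorded so
  the original distribution is recoverable. Remainders after rounding
  go to the largest fractional parts, ties to earlier bins.
* **Splits**: patients (never rows) are assigned to 5 outer × 5 inner
  folds; patients are ordered by mean target pH and consecutive blocks
  are dealt across folds in random order, which keeps each fold's
  pH-range composition within a few points of the global one without an
  explicit constraint solver.

## Numerical conventions

Quantiles are type 7 (linear interpolation) everywhere — small-bin 95th
percentiles are method-sensitive, so the choice is fixed and documented.
pH range boundaries are <7.3, [7.3, 7.45), ≥7.45; PCO₂ ranges
[20,35), [35,60), [60,120]. Range coverage counts a prediction as
correct when its interval intersects the truth's bin
([a,b] meets [lo,hi) iff b ≥ lo and a < hi); zero half-width reduces to
point-in-bin. The Mann–Whitney comparison uses `stats::wilcox.test`
(exact at small n without ties, normal approximation with tie
correction otherwise); an exact enumeration oracle cross-checks it in
the tests. Zero-variance predictors get unit scale so constant columns
survive standardization; the singular λ = 0 ridge system raises an
error that recommends λ > 0. Seeded helpers restore the caller's RNG
state, and the pipeline fans one master seed out to per-stage child
seeds so stages can be re-run independently.

## Problem sizes

The test suite and acceptance script run on simulated cohorts of 60–500
patients (roughly 300–2,600 feature rows), five replicate seeds for the
stochastic properties, and a 63-point hyperparameter grid — sizes chosen
so the complete suite runs in about a minute on one core while keeping
every per-bin statistic reasonably populated (the lag analysis flags
bins under 20 samples as low-n).

## Known limitations

* Estimation requires at least one recent invasive blood gas; patients
  without one are out of scope by design.
* The importance formula reports contribution shifts, not causal
  effects; correlated predictors share credit as ridge assigns it.
* The error-bound calibration optimizes a tail statistic on finite
  calibration data; on small calibration sets the achieved validation
  rate can differ from the calibrated one by a few points.
* Capillary and arterial samples are treated interchangeably (they are
  generated identically and only flagged), so capillary-specific bias
  is not modeled.
* The simulator's realism is structural, not distributional: its cohort
  medians track published pediatric ICU summaries, but no claim is made
  that model accuracy on it transfers to clinical data.
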