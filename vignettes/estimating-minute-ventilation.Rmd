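---
title: "Estimating minute ventilation from wearable data: models, validation and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating minute ventilation from wearable data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventdose)
```

## The problem

Air-pollution inhaled dose is the time-integral of pollutant
concentration times minute ventilation (V̇E, the volume of air inhaled
per minute). Concentration is routinely measured by personal monitors;
V̇E is not, because direct measurement needs a mask or mouthpiece.
`ventdose` estimates V̇E from predictors that consumer and medical
wearables measure continuously — heart rate (HR) and breath frequency
(f_B) — combined with stable subject traits: age, sex and forced vital
capacity (FVC), the functional lung size that scales how much air a
breath can move.

## Model and assumptions

The response and all predictors enter on the log scale:

$$\ln \dot V_E = \beta_0 + \beta_1 \ln HR + \beta_2 \ln f_B +
\beta_3 \ln age + \beta_4 \ln sex + \beta_5 \ln FVC +
u_{0i} + u_{1i}\ln HR + u_{2i}\ln f_B + \varepsilon$$

so the fixed effects define a power function
$\dot V_E = e^{\beta_0} HR^{\beta_1} f_B^{\beta_2} age^{\beta_3}
sex^{\beta_4} FVC^{\beta_5}$. Assumptions, and why this form:

* **Positivity.** Exponentiating a linear predictor can never produce a
  negative ventilation, unlike linear models of V̇E, which misbehave at
  resting heart rates.
* **Implicit interactions.** Because
  $\ln(HR \cdot f_B) = \ln HR + \ln f_B$ exactly, a log-log model needs
  no explicit interaction or quadratic terms: any such column is a
  linear combination of columns already present and leaves the
  fitted-value space unchanged (the exponents simply recombine,
  $\beta_1' = \beta_1 + \beta_3$). The test suite verifies this with a
  rank-revealing least-squares oracle.
* **Between-subject heterogeneity.** The V̇E–HR relationship differs
  strongly between people. A per-subject random intercept plus random
  slopes on $\ln HR$ and $\ln f_B$ model that heterogeneity; the three
  effects are mutually independent (variance-components covariance).
  Serial (AR-type) residual correlation is deliberately not modelled.
* **Sex coding.** Sex enters as the logarithm of a 1/2 code (1 male,
  2 female). $\ln 1 = 0$, so male predictions are independent of
  $\beta_4$ and the female/male ratio is exactly $2^{\beta_4}$. This is
  numerically identical to a scaled indicator and is kept so published
  coefficients are reproducible digit for digit.
* **Log-normal residuals**, i.e. multiplicative errors of constant
  relative magnitude — appropriate for a quantity spanning 5–150 L/min.

Two fitted instances are built in: `model_d1()` (HR only,
$e^{-9.59} HR^{2.39} age^{0.274} sex^{-0.204} FVC^{0.520}$) and
`model_d2()` (adds f_B,
$e^{-8.57} HR^{1.72} f_B^{0.611} age^{0.298} sex^{-0.206} FVC^{0.614}$).
D2 is the more precise; D1 exists because many field deployments record
HR only. Six published comparison models are available through
`legacy_models()` for benchmarking; the linear one among them can
produce non-positive values at rest, which the package flags rather
than silently clamps (an opt-in `clamp` exists).

## FVC: measured, predicted, and the reference table

FVC appears as a predictor because tidal volume scales with lung size.
When spirometry is unavailable, FVC is predicted from height, age, sex
and ancestry group using the GLI functional form
$\exp(a_0 + a_1 \ln height + a_2 \ln age + s(age))$ with the
age-varying contribution $s(\cdot)$ consumed as a tabulated lookup and
interpolated linearly in age — published equation sets ship exactly such
lookup tables, and linear interpolation keeps the implementation
table-agnostic. Ancestry labels map to the five reference groups by
`map_to_gli_group()`: white → Caucasian, African(-American) ancestry →
AfricanAmerican, and labels that cannot identify a specific group
(bare "Asian", "Hispanic", empty) → Other, which is the only safe total
default.

The packaged table (`gli_reference_table()`) is **synthetic**: it uses
the GLI form with coefficients calibrated to physiologic adult volumes
(≈5.5 L male / 3.8 L female FVC at reference height and age 30, FEV₁ =
0.8·FVC, a mild decline after mid-adulthood). It exists so every
pipeline is runnable and testable offline; its values are not those of
any published equation set, and analyses intended for publication should
load one with `read_reference_table()` or rely on measured FVC.

`resolve_fvc()`'s default policy prefers measured FVC: reference
equations are accurate *on average* but individuals deviate by roughly
±10%, and that deviation propagates into V̇E error with exponent ≈0.6.
`classify_fvc_status()` stratifies subjects at <85% and >115% of
predicted (both boundaries inclusive in "normal" — the outer strata are
defined by strict inequalities), which is how stratified performance
tables are built.

## Fitting, inference and numerical choices

* **Estimation.** `fit_loglog_lmm()` wraps `lme4::lmer()`. Reported
  estimates and intervals use REML (the customary default for reporting
  mixed-model estimates); `lrt_fixed()` compares nested fixed-effect
  structures and refits with ML automatically, since REML likelihoods
  are not comparable across fixed structures. Wald 95% intervals on the
  log scale are used; with thousands of records per fit the difference
  from profile intervals is negligible.
* **Determinism.** The optimizer starts deterministically; fitting the
  same data twice gives identical estimates. A boundary (singular) fit —
  a variance component estimated at zero, common in small simulations —
  is reported with a warning but is a valid optimum, distinct from a
  convergence failure.
* **Row selection.** Records missing the response or any required
  predictor are excluded from fitting and counted (`n_excluded`); they
  remain available for prediction. At least two subjects with two usable
  records each are required.
* **Quantile rule.** Percent-error medians and IQRs use
  linear-interpolation quantiles (R type 7), configurable because
  printed IQRs depend on the rule. An exact-zero percent error counts as
  an over-prediction so the over/under split always sums to 100%; the
  ±25% tails use inclusive inequalities.
* **Cross-validation.** Folds partition *subjects*, never records;
  record-level folds would leak within-person structure and flatter any
  model. Held-out subjects are predicted at the population level
  (random effects zero) — the only prediction available for someone the
  model has never seen, and therefore the honest estimate of
  new-subject performance. Group mode (one fold per study, sex, ...)
  reproduces leave-one-group-out designs.
* **Dose.** Incremental dose is
  `concentration [µg/m³] × V̇E [L/min] × 1 min × 10⁻³ m³/L`, summed at
  the data's native one-minute resolution. Gaps are never interpolated:
  interpolating exposure would fabricate dose, so uncovered minutes are
  counted and reported instead.

## The synthetic-data generator

`simulate_dataset()` generates cohorts with exactly the statistical
structure the model assumes: demographics drawn to resemble a diverse
pooled cohort (ages 4–80 with a young-adult mode, sexes balanced,
heights ≈163 ± 18 cm marginally once children are included), a
rest → monotone ramp → recovery HR protocol of ~31 minutes (resting
HR ≈65, peak capped at 0.92·(220 − age), a conventional physiologic
ceiling), breath frequency coupled to HR as
`f_B = max(8, 2 + 0.18·HR + noise)` spanning the physiologic 10–60
range, and V̇E from the configured power law (default: the D2
constants) with per-subject random effects and log-normal residuals.
Default SDs — 0.3 (intercept), 0.1 (each slope), 0.15 (residual) on the
log scale — were chosen once as a realistic level of between-subject
heterogeneity for pooled multi-study physiology; about 17% of subjects
receive a "measured" FVC equal to predicted × (1 + δ), δ ~ N(0, 0.10),
mirroring the typical scatter of reference-equation predictions.

What passing tests on simulated data do show: the fitting code recovers
the generating parameters (each coefficient within 2·SE of truth in
≥90% of 20 seeds at 200 subjects; exact recovery in the noise-free
limit), and the full simulate → fit → 10-fold CV pipeline is unbiased
(|median percent error| < 5%). What they do not show: robustness to
features real data have and the generator does not — device error,
sub-minute dynamics and lag structure between HR and f_B,
anxiety/noise-driven ventilation unrelated to activity, and real joint
demographic distributions. The generator's between-subject spread is
deliberately generous, so simulated CV IQRs run wider than those
typically reported for real pooled cohorts; the IQR is a property of
the configured variances, not a target.

## Design choices where the design was open

* Deposited pooled files vary in layout, so ingest is driven by a
  column map (`default_column_map()`) with auto-detected comma/tab
  delimiters; subject traits may live in a second file or be repeated
  per row in a flat file. A `session` column is honoured when mapped
  (minutes are keyed by subject × session), since pooled deposits may
  contain repeated sessions per person.
* Sub-minute samples are averaged arithmetically within calendar
  minutes (median by option); a minute must contain at least one valid
  HR sample to exist.
* Records without f_B are retained — they are fully usable for HR-only
  models — and f_B-dependent models simply skip them. The benchmark
  runner can instead restrict all models to the common f_B subset
  (`records = "fb_subset"`) when strict comparability matters, because
  the choice of record set moves benchmark medians by a few points.
* Units are treated as consistent (V̇E in L/min, FVC in liters) without
  converting between body-temperature and standard conditions; inputs
  are assumed to share a convention.
* An optional resting floor (clamping predictions below 0.78·FVC, the
  empirical minimum resting ventilation as a fraction of lung size) is
  available for linear-family models but off by default: power-function
  models cannot go non-positive, which removes the floor's main
  justification.

## Problem sizes used by the test suite

Module tests use 10–40 simulated subjects; the deeper end-to-end checks
use 200 subjects × ~31 minutes (≈6,200 records) per fit, 20 seeds for
parameter-recovery coverage, and one 10-fold CV at 200 subjects —
sizes chosen to estimate all variance components stably while keeping a
full run around half a minute.

## Limitations

The built-in D1/D2 coefficients were estimated in healthy volunteers
whose ventilation was driven by physical activity; they will be less
accurate for ventilation driven by stress, noise or anxiety, and for
people whose measured lung function departs strongly from demographic
predictions unless measured FVC is supplied. The packaged reference
table is synthetic (see above). Dose computation is intake dose only —
no respiratory-tract deposition modelling — and is validated by its
algebraic properties (additivity, scale equivariance, unit factor)
rather than against an external gold standard.
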