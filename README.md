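# ventdose

Estimate minute ventilation (V̇E, L·min⁻¹) from predictors that wearable
devices measure easily — heart rate, breath frequency, age, sex and forced
vital capacity — and use it to compute air-pollution **inhaled dose**,
the time-integral of pollutant concentration × ventilation rate.

Exposure-science and panel studies rarely measure V̇E directly: doing so
requires a mask or mouthpiece that is intrusive outside the lab. But
inhaled dose depends on V̇E, and the V̇E–HR relationship varies widely
between people, so a model that pools easy-to-measure predictors with
proper between-subject structure is needed. `ventdose` is for
epidemiologists, exposure scientists and exercise physiologists who have
per-minute wearable data and want defensible V̇E estimates and doses.

## The model

Everything centres on power-function models obtained by fitting a linear
mixed model on the log scale:

```
ln V̇E = β₀ + β₁ ln HR + β₂ ln f_B + β₃ ln age + β₄ ln sex + β₅ ln FVC
        + u₀ᵢ + u₁ᵢ ln HR + u₂ᵢ ln f_B + ε
```

equivalently `V̇E = e^β₀ · HR^β₁ · f_B^β₂ · age^β₃ · sex^β₄ · FVC^β₅`,
with per-subject random intercept `u₀ᵢ` and random slopes `u₁ᵢ`, `u₂ᵢ`
(mutually independent, variance-components covariance), sex coded 1 for
males and 2 for females, and FVC in liters. The log-log form keeps
predictions positive and absorbs interaction and higher-order terms:
`ln(HR·f_B)` is exactly `ln HR + ln f_B`, so explicit interaction columns
add nothing to the fitted-value space.

Two fitted instances ship as built-in constants:

* **Model D1** (HR only, for when no breathing sensor is worn):
  `V̇E = e^−9.59 HR^2.39 age^0.274 sex^−0.204 FVC^0.520`
* **Model D2** (HR + breath frequency, more precise):
  `V̇E = e^−8.57 HR^1.72 f_B^0.611 age^0.298 sex^−0.206 FVC^0.614`

When FVC is not measured by spirometry it is predicted from height, age,
sex and ancestry group with GLI-style reference equations
(`predict_fvc()`); measured FVC is preferred when available
(`resolve_fvc()`), because measured-vs-predicted discrepancies translate
directly into over-/under-prediction of V̇E. Six previously published
comparison models (Zuurbier, Ramos, Cozza, Do Vale, McArdle, Greenwald)
are included for benchmarking (`legacy_models()`).

The packaged reference-equation table is **synthetic** (same functional
form as GLI, coefficients calibrated to physiologic adult volumes); for
production estimates load a published table via `read_reference_table()`
or supply measured FVC.

## Worked example

```r
library(ventdose)

# Closed-form prediction: a 30-year-old man, HR 100, FVC 5 L
predict_ve(model_d1(), hr = 100, age = 30, sex = 1, fvc = 5)
#> [1] 24.17194     # L/min

# A woman, FVC 4.2 L, over a light -> hard exercise ramp
predict_ve(model_d2(), hr = c(80, 120, 160), fb = c(16, 26, 40),
           age = 30, sex = 2, fvc = 4.2)
#> [1] 11.16795 30.17740 64.40007

# Refit the model on (here: simulated) pooled per-minute data
sim <- simulate_dataset(simulation_config(n_subjects = 60), seed = 7)
fit <- fit_loglog_lmm(sim$dataset, d2_formula())
fit
#> <ve_fit> log-log linear mixed model (REML)
#>   n_obs = 1871, n_subjects = 60, excluded = 0
#>         term estimate    se  lower  upper
#>  (Intercept)   -8.393 0.376 -9.129 -7.657
#>        ln_hr    1.702 0.037  1.630  1.774
#>        ln_fb    0.599 0.038  0.525  0.673
#>       ln_age    0.225 0.148 -0.065  0.514
#>       ln_sex   -0.022 0.224 -0.460  0.417
#>       ln_fvc    0.648 0.305  0.049  1.246

# Subject-grouped 10-fold cross-validation (no leakage across folds)
cv <- cross_validate(sim$dataset, d2_formula(),
                     make_folds(sim$dataset$subjects, k = 10, seed = 7))
cv
#> <cv_report> 10-fold subject-grouped cross-validation
#>   percent error median(IQR) = 1.13(117)%, over(under) = 51(49)%, n = 1871

# Inhaled dose: one hour at 35 ug/m3 during an exercise ramp
sub <- subject_table("A", age = 30, sex_code = 1, height = 175,
                     ethnicity = "Caucasian")
rec <- data.frame(minute_index = 1:60, hr = seq(70, 129),
                  fb = seq(14, 43.5, by = 0.5))
estimate_dose(rec, sub, exposure_series(1:60, rep(35, 60)),
              model = model_d2())
#> <dose_result> total inhaled dose = 69.56 ug over 60 min
```

The fitted exponents recover the generating (D2) values within their
standard errors; the CV median percent error near zero says the
population-level predictions are unbiased for new subjects, while the
IQR reflects the configured between-subject variability. Each minute of
dose is `concentration × V̇E × 10⁻³` µg, summed over covered minutes.

A command-line front end covering simulate / ingest / fit /
cross-validate / benchmark / predict / dose lives at
`inst/cli/ventdose` (see its header for usage).

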