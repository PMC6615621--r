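# Closed-form minute-ventilation models.
#
# The central object is the power-function model
#   VE = exp(b0) * HR^b1 * fB^b2 * age^b3 * sex^b4 * FVC^b5
# (sex coded 1 male / 2 female; FVC in liters), the exponentiated form of
# a linear model in logs.  Two fitted instances ship as constants (the
# HR-only model D1 and the HR+fB model D2), alongside six previously
# published comparison models in their original functional forms.

# Published coefficient constants.  These must match the checked-in
# inst/extdata/published_models.json digit for digit (tested).
.d1_coefs <- c(intercept = -9.59, hr = 2.39, age = 0.274,
               sex = -0.204, fvc = 0.520)
.d2_coefs <- c(intercept = -8.57, hr = 1.72, fb = 0.611, age = 0.298,
               sex = -0.206, fvc = 0.614)

#' Construct a power-function ventilation model
#'
#' @param name Model label.
#' @param intercept Intercept `b0` on the log(L/min) scale.
#' @param exponents Named numeric vector of exponents; names from
#'   `c("hr", "fb", "age", "sex", "fvc")`.
#' @param required Predictors that must be supplied at prediction time;
#'   defaults to every predictor with an exponent.
#' @return Object of class `power_function_model`.
#' @examples
#' m <- power_function_model("toy", intercept = 0, exponents = c(hr = 1))
#' predict_ve(m, hr = 10)  # 10 L/min
#' @export
power_function_model <- function(name, intercept, exponents,
                                 required = names(exponents)) {
  allowed <- c("hr", "fb", "age", "sex", "fvc")
  if (is.null(names(exponents)) || !all(names(exponents) %in% allowed))
    stop_input("exponents must be named from: ",
               paste(allowed, collapse = ", "))
  if (!all(required %in% names(exponents)))
    stop_input("every required predictor needs an exponent")
  structure(list(name = name, intercept = as.numeric(intercept),
                 exponents = exponents, required = required),
            class = "power_function_model")
}

#' @export
print.power_function_model <- function(x, ...) {
  terms <- paste0(names(x$exponents), "^", signif(x$exponents, 4),
                  collapse = " * ")
  cat("<power_function_model> ", x$name, "\n  VE = e^", x$intercept, " * ",
      terms, "  [L/min]\n", sep = "")
  invisible(x)
}

#' Built-in fitted models D1 (HR-only) and D2 (HR + breath frequency)
#'
#' `model_d1()` uses heart rate as the only continuously measured
#' predictor: `VE = e^-9.59 HR^2.39 age^0.274 sex^-0.204 FVC^0.520`.
#' `model_d2()` adds breath frequency:
#' `VE = e^-8.57 HR^1.72 fB^0.611 age^0.298 sex^-0.206 FVC^0.614`.
#' Units: HR beats/min, fB breaths/min, age years, sex 1 male / 2 female,
#' FVC liters; VE in L/min.
#'
#' @return A `power_function_model`.
#' @export
model_d1 <- function() {
  power_function_model("D1", .d1_coefs[["intercept"]],
                       .d1_coefs[setdiff(names(.d1_coefs), "intercept")])
}

#' @rdname model_d1
#' @export
model_d2 <- function() {
  power_function_model("D2", .d2_coefs[["intercept"]],
                       .d2_coefs[setdiff(names(.d2_coefs), "intercept")])
}

#' Predict minute ventilation with a power-function model
#'
#' Evaluates `exp(b0) * prod(x_i^b_i)` over the model's required
#' predictors.  All required predictors must be supplied and strictly
#' positive; a missing one raises an error rather than silently dropping
#' the term (a model that needs breath frequency cannot be evaluated
#' without it).
#'
#' @param model A [power_function_model()].
#' @param hr Heart rate, beats/min.
#' @param fb Breath frequency, breaths/min (if the model requires it).
#' @param age Age, years.
#' @param sex Sex code: 1 male, 2 female.
#' @param fvc Forced vital capacity, liters.
#' @return Numeric vector of VE in L/min (always positive).
#' @examples
#' predict_ve(model_d1(), hr = 100, age = 30, sex = 1, fvc = 5)
#' @export
predict_ve <- function(model, hr = NULL, fb = NULL, age = NULL,
                       sex = NULL, fvc = NULL) {
  stopifnot(inherits(model, "power_function_model"))
  supplied <- list(hr = hr, fb = fb, age = age, sex = sex, fvc = fvc)
  miss <- model$required[vapply(model$required,
                                function(p) is.null(supplied[[p]]), TRUE)]
  if (length(miss))
    stop_input("model '", model$name, "' requires predictor(s): ",
               paste(miss, collapse = ", "))
  vals <- supplied[model$required]
  n <- max(vapply(vals, length, 0L))
  lp <- rep(model$intercept, n)
  for (p in model$required) {
    x <- rep_len(as.numeric(vals[[p]]), n)
    if (any(is.na(x) | x <= 0))
      stop_input("predictor '", p, "' must be strictly positive ",
                 "(power-function models are defined on logs)")
    lp <- lp + model$exponents[[p]] * log(x)
  }
  exp(lp)
}

# ---- previously published comparison models --------------------------

#' Registry of previously published VE models
#'
#' Six published predictive models, each in its original functional form
#' and with its published coefficients:
#' \describe{
#'   \item{zuurbier}{sex-stratified log-linear in HR:
#'     males `e^(1.03 + 0.021 HR)`, females `e^(0.57 + 0.023 HR)`}
#'   \item{ramos}{sex-stratified log-linear in HR:
#'     males `e^(1.17 + 0.02 HR)`, females `e^(0.99 + 0.02 HR)`}
#'   \item{cozza}{log-linear in HR: `e^(0.58 + 0.025 HR)`}
#'   \item{do_vale}{power in HR: `0.00071 * HR^2.17`}
#'   \item{mcardle}{breath-frequency only:
#'     `fB * (1.8028 ln(fB) - 3.8881)`}
#'   \item{greenwald2014}{linear: `-4.247 + 0.0595 HR + 0.226 fB`; can go
#'     non-positive at low inputs, which is flagged, not clamped}
#' }
#'
#' @return Named list of `legacy_model` objects with fields `model_id`,
#'   `label`, `family`, `coefficients` and `required`.
#' @export
legacy_models <- function() {
  lm_spec <- function(model_id, label, family, coefficients, required) {
    structure(list(model_id = model_id, label = label, family = family,
                   coefficients = coefficients, required = required),
              class = "legacy_model")
  }
  list(
    zuurbier = lm_spec("zuurbier", "Zuurbier et al.", "sex_loglinear_hr",
      list(male = c(a = 1.03, b = 0.021), female = c(a = 0.57, b = 0.023)),
      c("hr", "sex")),
    ramos = lm_spec("ramos", "Ramos et al.", "sex_loglinear_hr",
      list(male = c(a = 1.17, b = 0.02), female = c(a = 0.99, b = 0.02)),
      c("hr", "sex")),
    cozza = lm_spec("cozza", "Cozza et al.", "loglinear_hr",
      c(a = 0.58, b = 0.025), "hr"),
    do_vale = lm_spec("do_vale", "Do Vale et al.", "power_hr",
      c(a = 0.00071, b = 2.17), "hr"),
    mcardle = lm_spec("mcardle", "McArdle et al.", "fb_log",
      c(a = 1.8028, b = 3.8881), "fb"),
    greenwald2014 = lm_spec("greenwald2014", "Greenwald et al.", "linear",
      c(a = -4.247, b_hr = 0.0595, b_fb = 0.226), c("hr", "fb"))
  )
}

#' Predict minute ventilation with a previously published model
#'
#' @param spec A `legacy_model` from [legacy_models()], or its id string.
#' @param hr Heart rate, beats/min.
#' @param fb Breath frequency, breaths/min.
#' @param sex Sex code (1 male, 2 female) for sex-stratified models.
#' @param clamp If `TRUE`, non-positive predictions (possible for the
#'   linear greenwald2014 model at low inputs) are clamped to `NA`;
#'   default returns the raw value with attribute `"nonpositive"` giving
#'   the affected indices.
#' @return Numeric vector of VE in L/min.
#' @examples
#' predict_ve_legacy("zuurbier", hr = 80, sex = 1)   # ~15.0
#' predict_ve_legacy("mcardle", fb = 12)             # ~7.10
#' @export
predict_ve_legacy <- function(spec, hr = NULL, fb = NULL, sex = NULL,
                              clamp = FALSE) {
  if (is.character(spec)) {
    reg <- legacy_models()
    if (!spec %in% names(reg))
      stop_input("unknown legacy model '", spec, "'; available: ",
                 paste(names(reg), collapse = ", "))
    spec <- reg[[spec]]
  }
  stopifnot(inherits(spec, "legacy_model"))
  if ("hr" %in% spec$required && is.null(hr))
    stop_input("model '", spec$model_id, "' requires hr")
  if ("fb" %in% spec$required && is.null(fb))
    stop_input("model '", spec$model_id, "' requires fb")
  if ("sex" %in% spec$required && is.null(sex))
    stop_input("model '", spec$model_id, "' is sex-stratified; supply sex")
  if (!is.null(sex) && !all(sex %in% c(1, 2)))
    stop_input("sex must be 1 or 2")

  ve <- switch(spec$family,
    sex_loglinear_hr = {
      n <- max(length(hr), length(sex))
      hr <- rep_len(hr, n); sex <- rep_len(sex, n)
      co <- spec$coefficients
      a <- ifelse(sex == 1, co$male["a"], co$female["a"])
      b <- ifelse(sex == 1, co$male["b"], co$female["b"])
      exp(a + b * hr)
    },
    loglinear_hr = exp(spec$coefficients["a"] + spec$coefficients["b"] * hr),
    power_hr = spec$coefficients["a"] * hr ^ spec$coefficients["b"],
    fb_log = fb * (spec$coefficients["a"] * log(fb) -
                     spec$coefficients["b"]),
    linear = {
      n <- max(length(hr), length(fb))
      spec$coefficients["a"] + spec$coefficients["b_hr"] * rep_len(hr, n) +
        spec$coefficients["b_fb"] * rep_len(fb, n)
    },
    stop_input("unknown model family '", spec$family, "'")
  )
  ve <- unname(ve)
  nonpos <- which(ve <= 0)
  if (length(nonpos)) {
    if (clamp) ve[nonpos] <- NA_real_
    else attr(ve, "nonpositive") <- nonpos
  }
  ve
}

#' Resolve which FVC value to use for prediction
#'
#' Measured FVC captures individual departures from the demographic
#' prediction (disease, genetic diversity), so the default policy prefers
#' it and falls back to the reference-equation prediction.
#'
#' @param measured Measured FVC in liters (`NA` when absent); vectorized.
#' @param predicted Predicted FVC in liters (`NA` when unavailable).
#' @param policy `"prefer_measured"` (default), `"predicted_only"` or
#'   `"measured_only"`.
#' @return `data.frame` with `fvc` (liters) and `fvc_source` (factor
#'   measured/predicted).  Errors if any subject has no value available
#'   under the chosen policy.
#' @export
resolve_fvc <- function(measured, predicted = NA_real_,
                        policy = c("prefer_measured", "predicted_only",
                                   "measured_only")) {
  policy <- match.arg(policy)
  n <- max(length(measured), length(predicted))
  measured <- rep_len(as.numeric(measured), n)
  predicted <- rep_len(as.numeric(predicted), n)
  fvc <- switch(policy,
    prefer_measured = ifelse(!is.na(measured), measured, predicted),
    predicted_only = predicted,
    measured_only = measured
  )
  src <- switch(policy,
    prefer_measured = ifelse(!is.na(measured), "measured", "predicted"),
    predicted_only = rep("predicted", n),
    measured_only = rep("measured", n)
  )
  if (any(is.na(fvc)))
    stop_input("no FVC available under policy '", policy, "' for ",
               sum(is.na(fvc)), " subject(s)")
  data.frame(fvc = fvc,
             fvc_source = factor(src, levels = c("measured", "predicted")))
}

#' Per-record VE predictions for a whole dataset
#'
#' Joins records to subjects, resolves FVC per the chosen policy (using
#' `reference_table` for predictions when needed) and evaluates the model
#' on every record with all required predictors present.
#'
#' @param ds A [physio_dataset()].
#' @param model A `power_function_model` or a `legacy_model` (or legacy id
#'   string).
#' @param fvc_policy Passed to [resolve_fvc()] (power-function models
#'   only; published comparison models do not use FVC).
#' @param reference_table Reference table used when predicted FVC is
#'   needed; defaults to the packaged synthetic table.
#' @return `data.frame` with one row per evaluable record: identifiers,
#'   predictors, `ve_pred` and (when applicable) `fvc`, `fvc_source`.
#' @export
predict_dataset <- function(ds, model,
                            fvc_policy = "prefer_measured",
                            reference_table = gli_reference_table()) {
  stopifnot(inherits(ds, "physio_dataset"))
  df <- merge(ds$records, as.data.frame(ds$subjects), by = "subject_id",
              sort = FALSE)
  if (is.character(model) || inherits(model, "legacy_model")) {
    if (is.character(model)) model <- legacy_models()[[model]]
    ok <- rep(TRUE, nrow(df))
    if ("fb" %in% model$required) ok <- ok & !is.na(df$fb)
    df <- df[ok, , drop = FALSE]
    df$ve_pred <- predict_ve_legacy(
      model,
      hr = if ("hr" %in% model$required) df$hr else NULL,
      fb = if ("fb" %in% model$required) df$fb else NULL,
      sex = if ("sex" %in% model$required) df$sex_code else NULL
    )
    attr(df$ve_pred, "nonpositive") <- NULL
    return(df)
  }
  stopifnot(inherits(model, "power_function_model"))
  if ("fvc" %in% model$required) {
    need_pred <- fvc_policy != "measured_only" &
      any(is.na(ds$subjects$measured_fvc))
    pred <- if (need_pred)
      predict_fvc(ds$subjects, reference_table) else NA_real_
    res <- resolve_fvc(ds$subjects$measured_fvc, pred, fvc_policy)
    res$subject_id <- ds$subjects$subject_id
    df <- merge(df, res, by = "subject_id", sort = FALSE)
  }
  if ("fb" %in% model$required) df <- df[!is.na(df$fb), , drop = FALSE]
  df$ve_pred <- predict_ve(
    model,
    hr = df$hr,
    fb = if ("fb" %in% model$required) df$fb else NULL,
    age = df$age,
    sex = df$sex_code,
    fvc = if ("fvc" %in% model$required) df$fvc else NULL
  )
  df
}
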