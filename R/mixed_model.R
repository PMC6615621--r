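# Log-log linear mixed models for minute ventilation.
#
# The response and all predictors are log-transformed, so the fixed
# effects define a power function of the predictors:
#   ln(VE) = b0 + b1 ln(HR) + b2 ln(fB) + b3 ln(age) + b4 ln(sex)
#            + b5 ln(FVC) + u0_i + u1_i ln(HR) + u2_i ln(fB) + e
# with per-subject random intercept u0 and random slopes u1 (and u2 when
# breath frequency is in the model), mutually independent (variance
# components covariance).  Log transformation makes interaction and
# higher-order terms implicit: a redundant ln(HR*fB) column is an exact
# linear combination of ln(HR) and ln(fB) and changes nothing about the
# fitted-value space.

#' Describe a log-log mixed-model formula
#'
#' @param predictors Character subset of `c("hr", "fb", "age", "sex",
#'   "fvc")` entering as log-transformed fixed effects.
#' @param random_slopes Predictors (subset of `c("hr", "fb")` present in
#'   `predictors`) that get independent per-subject random slopes, in
#'   addition to the always-present random intercept.  Default: every
#'   continuously measured predictor in the model.
#' @return Object of class `ve_formula`.
#' @examples
#' d1_formula()
#' ve_formula(c("hr", "age"))
#' @export
ve_formula <- function(predictors,
                       random_slopes = intersect(c("hr", "fb"),
                                                 predictors)) {
  allowed <- c("hr", "fb", "age", "sex", "fvc")
  if (!length(predictors) || !all(predictors %in% allowed))
    stop_input("predictors must be a non-empty subset of: ",
               paste(allowed, collapse = ", "))
  if (!all(random_slopes %in% intersect(c("hr", "fb"), predictors)))
    stop_input("random slopes only on hr/fb terms present in the model")
  structure(list(predictors = unique(predictors),
                 random_slopes = unique(random_slopes)),
            class = "ve_formula")
}

#' @rdname ve_formula
#' @export
d1_formula <- function() ve_formula(c("hr", "age", "sex", "fvc"))

#' @rdname ve_formula
#' @export
d2_formula <- function() ve_formula(c("hr", "fb", "age", "sex", "fvc"))

#' @export
print.ve_formula <- function(x, ...) {
  cat("<ve_formula> ln(ve) ~ ",
      paste0("ln(", x$predictors, ")", collapse = " + "),
      " + (1|subject)",
      paste0(vapply(x$random_slopes,
                    function(p) paste0(" + (0+ln(", p, ")|subject)"), ""),
             collapse = ""),
      "\n", sep = "")
  invisible(x)
}

as_lmer_formula <- function(formula) {
  fixed <- paste0("ln_", formula$predictors, collapse = " + ")
  rand <- paste0("(1 | subject_id)",
                 paste0(vapply(formula$random_slopes,
                               function(p) paste0(" + (0 + ln_", p,
                                                  " | subject_id)"), ""),
                        collapse = ""))
  stats::as.formula(paste("ln_ve ~", fixed, "+", rand))
}

# Build the log-scale model frame: one row per record with ve_observed and
# every required predictor present and positive.
build_model_frame <- function(ds, formula, fvc_policy, reference_table) {
  df <- merge(ds$records, as.data.frame(ds$subjects), by = "subject_id",
              sort = FALSE)
  if ("fvc" %in% formula$predictors) {
    need_pred <- fvc_policy != "measured_only" &&
      any(is.na(ds$subjects$measured_fvc))
    pred <- if (need_pred) predict_fvc(ds$subjects, reference_table)
      else NA_real_
    res <- resolve_fvc(ds$subjects$measured_fvc, pred, fvc_policy)
    res$subject_id <- ds$subjects$subject_id
    df <- merge(df, res, by = "subject_id", sort = FALSE)
  }
  ok <- !is.na(df$ve_observed)
  src <- list(hr = df$hr, fb = df$fb, age = df$age, sex = df$sex_code,
              fvc = df$fvc)
  for (p in formula$predictors) ok <- ok & !is.na(src[[p]]) & src[[p]] > 0
  mf <- df[ok, , drop = FALSE]
  mf$ln_ve <- log(mf$ve_observed)
  for (p in formula$predictors)
    mf[[paste0("ln_", p)]] <- log(switch(p, sex = mf$sex_code,
                                         mf[[p]]))
  attr(mf, "n_excluded") <- nrow(df) - nrow(mf)
  mf
}

#' Fit a log-log linear mixed model for minute ventilation
#'
#' Fits `ln(ve_observed)` on the log-transformed predictors with a
#' per-subject random intercept and independent per-subject random slopes
#' on ln(HR) (and ln(fB) when present), using [lme4::lmer()].  Records
#' missing any required field are excluded and counted.  REML is used for
#' reported estimates by default; [lrt_fixed()] refits with ML when
#' comparing fixed-effect structures.
#'
#' @param ds A [physio_dataset()] with observed VE.
#' @param formula A [ve_formula()]; default [d2_formula()].
#' @param fvc_policy How to resolve each subject's FVC, see
#'   [resolve_fvc()].
#' @param reference_table Reference table for predicted FVC.
#' @param REML Logical; `FALSE` gives maximum likelihood.
#' @return Object of class `ve_fit`: `coefficients` (estimate, SE, Wald
#'   95% CI per fixed term), `random_variances` (named variances incl.
#'   residual), `logLik`, `n_obs`, `n_subjects`, `n_excluded`,
#'   `converged`, `singular`, `REML`, `formula` and the underlying
#'   `merMod` as `fit`.
#' @export
fit_loglog_lmm <- function(ds, formula = d2_formula(),
                           fvc_policy = "prefer_measured",
                           reference_table = gli_reference_table(),
                           REML = TRUE) {
  stopifnot(inherits(ds, "physio_dataset"), inherits(formula, "ve_formula"))
  mf <- build_model_frame(ds, formula, fvc_policy, reference_table)
  per_subj <- table(mf$subject_id)
  if (length(per_subj) < 2L || sum(per_subj >= 2L) < 2L)
    stop_input("need at least 2 subjects with at least 2 usable records ",
               "each (got ", length(per_subj), " subject(s))")
  fit <- lme4::lmer(as_lmer_formula(formula), data = mf, REML = REML,
                    control = lme4::lmerControl(calc.derivs = FALSE))
  singular <- lme4::isSingular(fit)
  if (singular)
    warning("random-effect covariance estimate is singular (a variance ",
            "component is zero)", call. = FALSE)
  # a boundary (singular) fit is a valid optimum, not a convergence failure
  conv_msgs <- setdiff(fit@optinfo$conv$lme4$messages,
                       grep("boundary", fit@optinfo$conv$lme4$messages,
                            value = TRUE))
  converged <- length(conv_msgs) == 0L
  if (!converged)
    warning("optimizer reported: ", paste(conv_msgs, collapse = "; "),
            call. = FALSE)

  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- stats::qnorm(0.975)
  coefs <- data.frame(
    term = names(est), estimate = unname(est), se = unname(se),
    lower = unname(est - z * se), upper = unname(est + z * se),
    row.names = NULL
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  rv <- stats::setNames(vc$vcov, ifelse(is.na(vc$var1), vc$grp,
                                        paste(vc$grp, vc$var1)))
  structure(list(
    coefficients = coefs, random_variances = rv,
    logLik = as.numeric(stats::logLik(fit)),
    n_obs = nrow(mf), n_subjects = length(per_subj),
    n_excluded = attr(mf, "n_excluded"),
    converged = converged, singular = singular, REML = REML,
    formula = formula, fvc_policy = fvc_policy, fit = fit
  ), class = "ve_fit")
}

#' @export
print.ve_fit <- function(x, ...) {
  cat("<ve_fit> log-log linear mixed model (",
      if (x$REML) "REML" else "ML", ")\n", sep = "")
  cat("  n_obs = ", x$n_obs, ", n_subjects = ", x$n_subjects,
      ", excluded = ", x$n_excluded, "\n", sep = "")
  co <- x$coefficients
  co[-1] <- lapply(co[-1], function(v) sprintf("%.3f", v))
  print(co, row.names = FALSE)
  cat("  random-effect variances:\n")
  print(round(x$random_variances, 4))
  invisible(x)
}

#' Likelihood-ratio test between nested fixed-effect structures
#'
#' Tests whether the extra fixed terms of `full` improve on `reduced`:
#' `p = P(chi2_df >= 2 (l_full - l_reduced))` with `df` the difference in
#' fixed-term count.  Fixed-effect likelihood ratios are only valid under
#' maximum likelihood; REML fits are refitted with ML automatically
#' (`auto_refit = TRUE`, the default) or refused.
#'
#' Both fits must use the same rows (same `n_obs`).
#'
#' @param full,reduced `ve_fit` objects; `reduced`'s predictors must be a
#'   proper subset of `full`'s.
#' @param auto_refit Refit REML fits with ML instead of erroring.
#' @return List with `statistic`, `df`, `p_value` and the ML
#'   log-likelihoods.
#' @export
lrt_fixed <- function(full, reduced, auto_refit = TRUE) {
  stopifnot(inherits(full, "ve_fit"), inherits(reduced, "ve_fit"))
  if (!all(reduced$formula$predictors %in% full$formula$predictors) ||
      length(setdiff(full$formula$predictors,
                     reduced$formula$predictors)) < 1L)
    stop_input("'reduced' fixed terms must be a proper subset of 'full'")
  if (full$n_obs != reduced$n_obs)
    stop_input("fits use different row sets (n_obs ", full$n_obs, " vs ",
               reduced$n_obs, "); refit both on the common rows")
  ml_loglik <- function(f, label) {
    if (!f$REML) return(f$logLik)
    if (!auto_refit)
      stop_input(label, " fit uses REML; fixed-effect LRT requires ML ",
                 "(set auto_refit = TRUE or refit with REML = FALSE)")
    as.numeric(stats::logLik(lme4::refitML(f$fit)))
  }
  ll_full <- ml_loglik(full, "'full'")
  ll_red <- ml_loglik(reduced, "'reduced'")
  df <- length(full$formula$predictors) - length(reduced$formula$predictors)
  stat <- max(0, 2 * (ll_full - ll_red))
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       logLik_full = ll_full, logLik_reduced = ll_red)
}

#' Export the fixed effects of a mixed-model fit as a power-function model
#'
#' Copies the intercept and each `ln_*` coefficient into a
#' [power_function_model()], so predictions for new subjects equal
#' `exp(fixed-effect linear predictor)` (random effects zero: the
#' population-level prediction, the only one available for subjects the
#' model was not trained on).
#'
#' @param fit A `ve_fit`.
#' @param name Name for the resulting model.
#' @return A `power_function_model`.
#' @export
as_power_model <- function(fit, name = "fitted") {
  stopifnot(inherits(fit, "ve_fit"))
  if (!fit$converged)
    warning("exporting a fit the optimizer flagged as not cleanly ",
            "converged", call. = FALSE)
  co <- fit$coefficients
  b0 <- co$estimate[co$term == "(Intercept)"]
  rest <- co[co$term != "(Intercept)", ]
  exponents <- stats::setNames(rest$estimate, sub("^ln_", "", rest$term))
  power_function_model(name, b0, exponents)
}
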