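# Synthetic-data generator.
#
# Emulates pooled per-minute exercise/ambulatory physiology with the
# statistical structure the mixed models assume: subjects with
# demographics drawn to mirror a diverse pooled cohort (ages 4-80, sexes
# balanced, height about 163 +/- 18 cm marginally), heart-rate
# trajectories over a rest / monotone-ramp / recovery protocol, breath
# frequency coupled to HR, and observed VE generated from a power law
# with per-subject random intercept and slopes plus log-normal residual
# noise — so the generating process is exactly the model family the
# fitting code estimates, which is what makes parameter-recovery and
# cross-validation self-consistency checks meaningful.

#' Configuration for the synthetic-data generator
#'
#' Defaults define the reference simulation conditions used throughout
#' the package's tests: the true model is the fitted HR+fB model
#' ([model_d2()]), log-scale random-effect SDs of 0.3 (intercept) and 0.1
#' (HR and fB slopes), log-scale residual SD 0.15, about 31 records per
#' subject, ages 4-80 years, and 17% of subjects carrying a "measured"
#' FVC equal to predicted times `(1 + delta)` with `delta ~ N(0, 0.10)`
#' (reference-equation predictions scatter about +/-10% around truth).
#'
#' @param n_subjects Number of subjects.
#' @param true_model [power_function_model()] generating VE.
#' @param sd_intercept,sd_slope_hr,sd_slope_fb Log-scale SDs of the
#'   mutually independent per-subject random intercept and slopes.
#' @param sd_residual Log-scale residual SD.
#' @param session_minutes Mean session length; segment lengths are drawn
#'   around a 5 rest / 20 ramp / 6 recovery split scaled to this mean.
#' @param age_range Sampled age range in years.
#' @param rest_hr Mean resting heart rate, beats/min.
#' @param fb_c0,fb_c1,fb_sd Breath-frequency coupling
#'   `fb = max(8, fb_c0 + fb_c1 * hr + N(0, fb_sd))`.
#' @param measured_fvc_fraction Share of subjects given a measured FVC.
#' @param fvc_meas_sd SD of the relative measured-vs-predicted deviation.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 200,
                              true_model = model_d2(),
                              sd_intercept = 0.3,
                              sd_slope_hr = 0.1,
                              sd_slope_fb = 0.1,
                              sd_residual = 0.15,
                              session_minutes = 31,
                              age_range = c(4, 80),
                              rest_hr = 65,
                              fb_c0 = 2, fb_c1 = 0.18, fb_sd = 2,
                              measured_fvc_fraction = 0.17,
                              fvc_meas_sd = 0.10) {
  stopifnot(n_subjects >= 1,
            sd_intercept >= 0, sd_slope_hr >= 0, sd_slope_fb >= 0,
            sd_residual >= 0,
            age_range[1] >= 4, age_range[2] <= 80,
            age_range[1] < age_range[2],
            measured_fvc_fraction >= 0, measured_fvc_fraction <= 1)
  stopifnot(inherits(true_model, "power_function_model"))
  structure(as.list(environment()), class = "simulation_config")
}

sample_profile <- function(i, config) {
  a <- config$age_range
  age <- a[1] + (a[2] - a[1]) * stats::rbeta(1, 1.5, 2.4)
  sex <- sample(1:2, 1)
  adult_height <- if (sex == 1) stats::rnorm(1, 177, 7)
    else stats::rnorm(1, 164, 7)
  height <- if (age >= 18) adult_height
    else 84 + (age / 18) * (adult_height - 84) + stats::rnorm(1, 0, 4)
  ethnicity <- sample(c("Caucasian", "African-American", "Hispanic",
                        "Asian"), 1,
                      prob = c(0.79, 0.042, 0.11, 0.058))
  data.frame(subject_id = sprintf("S%04d", i), age = age,
             sex_code = sex, height = max(height, 80),
             weight = max(20, 0.38 * height - 2 + stats::rnorm(1, 0, 8)),
             ethnicity = ethnicity, country = "US",
             study_id = sprintf("study%d", 1 + (i - 1) %% 8),
             stringsAsFactors = FALSE)
}

# Rest plateau, strictly non-decreasing ramp, exponential recovery.
simulate_hr_trajectory <- function(age, config) {
  m <- config$session_minutes
  n_rest <- max(2L, round(stats::rnorm(1, 5 * m / 31, 1)))
  n_ramp <- max(5L, round(stats::rnorm(1, 20 * m / 31, 2)))
  n_rec <- max(2L, round(stats::rnorm(1, 6 * m / 31, 1)))
  rest <- stats::rnorm(1, config$rest_hr, 5)
  peak <- min(0.92 * (220 - age), rest + 60 + stats::rnorm(1, 45, 10))
  peak <- max(peak, rest + 25)
  hr_rest <- rest + stats::rnorm(n_rest, 0, 1.5)
  inc <- stats::rgamma(n_ramp, shape = 2)
  ramp <- rest + (peak - rest) * cumsum(inc) / sum(inc)
  rec <- rest + 20 + (peak - rest - 20) * exp(-(seq_len(n_rec)) / 3) +
    stats::rnorm(n_rec, 0, 2)
  pmax(c(hr_rest, ramp, rec), 40)
}

#' Simulate one subject's session
#'
#' Generates the subject's HR trajectory, coupled breath frequency, and
#' observed VE from the configured power law with this subject's random
#' effects and log-normal residual noise:
#' `ln VE = (b0 + u0) + (b_hr + u_hr) ln HR + (b_fb + u_fb) ln fB`
#' `+ b_age ln age + b_sex ln sex + b_fvc ln FVC + e`.
#' Terms absent from the true model drop out.  With all SDs zero the
#' records satisfy the power law exactly.
#'
#' @param profile One-row subject data.frame (see
#'   [simulation_config()]; FVC fields are added here).
#' @param config A `simulation_config`.
#' @param reference_table Reference table for the subject's predicted
#'   (and hence true) FVC.
#' @param seed Optional seed (RNG state restored).
#' @return List with `subject` (profile incl. `measured_fvc`), `records`
#'   and `random_effects`.
#' @export
simulate_subject_session <- function(profile, config,
                                     reference_table =
                                       gli_reference_table(),
                                     seed = NULL) {
  with_seed(seed, {
    exps <- config$true_model$exponents
    u <- c(
      intercept = stats::rnorm(1, 0, config$sd_intercept),
      hr = if ("hr" %in% names(exps))
        stats::rnorm(1, 0, config$sd_slope_hr) else 0,
      fb = if ("fb" %in% names(exps))
        stats::rnorm(1, 0, config$sd_slope_fb) else 0
    )
    hr <- simulate_hr_trajectory(profile$age, config)
    n <- length(hr)
    fb <- pmax(8, config$fb_c0 + config$fb_c1 * hr +
                 stats::rnorm(n, 0, config$fb_sd))
    pred_fvc <- predict_fvc(profile, reference_table)
    has_meas <- stats::runif(1) < config$measured_fvc_fraction
    measured_fvc <- if (has_meas)
      pred_fvc * (1 + stats::rnorm(1, 0, config$fvc_meas_sd)) else NA_real_
    true_fvc <- if (has_meas) measured_fvc else pred_fvc

    lp <- config$true_model$intercept + u[["intercept"]]
    term <- function(name, x, slope_re = 0)
      if (name %in% names(exps)) (exps[[name]] + slope_re) * log(x) else 0
    lp <- lp + term("hr", hr, u[["hr"]]) + term("fb", fb, u[["fb"]]) +
      term("age", profile$age) + term("sex", profile$sex_code) +
      term("fvc", true_fvc)
    ve <- exp(lp + stats::rnorm(n, 0, config$sd_residual))

    subject <- profile
    subject$measured_fvc <- measured_fvc
    subject$measured_fev1 <- if (has_meas) measured_fvc * 0.8 else NA_real_
    list(
      subject = subject,
      records = data.frame(subject_id = profile$subject_id,
                           minute_index = seq_len(n), hr = hr, fb = fb,
                           ve_observed = ve, stringsAsFactors = FALSE),
      random_effects = data.frame(subject_id = profile$subject_id,
                                  u_intercept = u[["intercept"]],
                                  u_hr = u[["hr"]], u_fb = u[["fb"]],
                                  true_fvc = true_fvc,
                                  stringsAsFactors = FALSE)
    )
  })
}

#' Simulate a pooled physiological dataset
#'
#' Draws `config$n_subjects` independent subjects and their sessions.
#' Regenerating with the same config and seed is bit-identical.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @param reference_table Reference table used for predicted FVC.
#' @return Object of class `simulated_dataset`: `dataset` (a
#'   [physio_dataset()]), `random_effects` (per-subject ground truth),
#'   `config`, `seed`.
#' @examples
#' sim <- simulate_dataset(simulation_config(n_subjects = 5), seed = 1)
#' sim$dataset
#' @export
simulate_dataset <- function(config = simulation_config(), seed = 1,
                             reference_table = gli_reference_table()) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(seed, {
    sessions <- lapply(seq_len(config$n_subjects), function(i)
      simulate_subject_session(sample_profile(i, config), config,
                               reference_table))
    subjects <- do.call(rbind, lapply(sessions, `[[`, "subject"))
    records <- do.call(rbind, lapply(sessions, `[[`, "records"))
    truth <- do.call(rbind, lapply(sessions, `[[`, "random_effects"))
    ds <- physio_dataset(
      records, validate_subject_table(subjects),
      provenance = list(source = "ventdose::simulate_dataset",
                        seed = seed)
    )
    structure(list(dataset = ds, random_effects = truth, config = config,
                   seed = seed), class = "simulated_dataset")
  })
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat("<simulated_dataset> seed ", x$seed, ", true model '",
      x$config$true_model$name, "'\n", sep = "")
  print(x$dataset)
  invisible(x)
}
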