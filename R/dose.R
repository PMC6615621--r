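# Inhaled-dose pipeline: align physiology and pollutant concentration on
# a one-minute grid and integrate dose = concentration x ventilation.

#' Construct a pollutant exposure series
#'
#' @param minute_index Integer minutes.
#' @param concentration Pollutant concentration in ug/m^3 (>= 0).
#' @return `data.frame` of class `exposure_series`, sorted by minute.
#' @export
exposure_series <- function(minute_index, concentration) {
  if (any(is.na(concentration) | concentration < 0))
    stop_input("concentrations must be non-negative")
  if (anyDuplicated(minute_index))
    stop_input("duplicate minute_index in exposure series")
  df <- data.frame(minute_index = as.integer(minute_index),
                   concentration = as.numeric(concentration))
  df <- df[order(df$minute_index), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("exposure_series", "data.frame")
  df
}

#' Read an exposure series from delimited text
#'
#' Expects columns for the minute (or a `time_s` seconds column, which is
#' floored to minutes and averaged within minute) and the concentration.
#'
#' @param path CSV/TSV file.
#' @param minute_col,conc_col Column names.
#' @return An [exposure_series()].
#' @export
read_exposure_series <- function(path, minute_col = "minute_index",
                                 conc_col = "concentration") {
  df <- read_delim_auto(path)
  if (!conc_col %in% names(df))
    stop_input("no concentration column '", conc_col, "' in ", path)
  if (minute_col %in% names(df)) {
    exposure_series(df[[minute_col]], df[[conc_col]])
  } else if ("time_s" %in% names(df)) {
    m <- floor(as.numeric(df$time_s) / 60)
    agg <- tapply(df[[conc_col]], m, mean)
    exposure_series(as.integer(names(agg)), as.numeric(agg))
  } else stop_input("no '", minute_col, "' or 'time_s' column in ", path)
}

#' Align physiological and exposure channels on the minute grid
#'
#' Inner-joins the channels a chosen model needs (HR always; breath
#' frequency only if `require_fb`) with the concentration series.
#' Minutes missing a required channel are dropped and counted by reason.
#'
#' @param hr `data.frame(minute_index, hr)`.
#' @param conc An [exposure_series()] or `data.frame(minute_index,
#'   concentration)`.
#' @param fb Optional `data.frame(minute_index, fb)`.
#' @param require_fb Does the prediction model need breath frequency?
#' @return `data.frame` of aligned minutes with attribute `skipped`
#'   (named counts: `no_hr`, `no_fb`, `no_concentration`).  Errors when no
#'   minute overlaps.
#' @export
align_to_minute_grid <- function(hr, conc, fb = NULL, require_fb = FALSE) {
  hr <- as.data.frame(hr); conc <- as.data.frame(conc)
  stopifnot(all(c("minute_index", "hr") %in% names(hr)),
            all(c("minute_index", "concentration") %in% names(conc)))
  out <- merge(hr[!is.na(hr$hr), c("minute_index", "hr")],
               conc[c("minute_index", "concentration")],
               by = "minute_index")
  if (require_fb) {
    if (is.null(fb)) stop_input("model requires fb but no fb series given")
    fb <- as.data.frame(fb)
    out <- merge(out, fb[!is.na(fb$fb), c("minute_index", "fb")],
                 by = "minute_index")
  } else if (!is.null(fb)) {
    out <- merge(out, as.data.frame(fb)[c("minute_index", "fb")],
                 by = "minute_index", all.x = TRUE)
  }
  all_minutes <- unique(c(hr$minute_index, conc$minute_index,
                          if (!is.null(fb)) fb$minute_index))
  skipped <- c(
    no_hr = sum(!(conc$minute_index %in% hr$minute_index[!is.na(hr$hr)])),
    no_concentration = sum(!(hr$minute_index %in% conc$minute_index)),
    no_fb = if (require_fb)
      sum(!(intersect(hr$minute_index, conc$minute_index) %in%
              fb$minute_index[!is.na(fb$fb)])) else 0L
  )
  if (nrow(out) == 0L)
    stop_input("no overlapping minutes between physiology and exposure")
  out <- out[order(out$minute_index), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Integrate inhaled dose over aligned minutes
#'
#' Incremental dose per minute is
#' `concentration [ug/m^3] * VE [L/min] * 1 [min] * 1e-3 [m^3/L]` and the
#' total is their sum (rectangle rule at the data's native one-minute
#' resolution; gaps are never interpolated — they simply contribute no
#' dose and are reported as uncovered).
#'
#' @param ve Per-minute VE in L/min: numeric vector aligned with `conc`,
#'   or `data.frame(minute_index, ve)` joined on minutes.
#' @param conc An [exposure_series()] (or data.frame with `minute_index`,
#'   `concentration`).
#' @return Object of class `dose_result`: `total_dose` (ug), `per_minute`
#'   table, `minutes_covered`, `minutes_skipped`.
#' @examples
#' conc <- exposure_series(1:60, rep(10, 60))
#' integrate_dose(rep(20, 60), conc)$total_dose  # 12 ug
#' @export
integrate_dose <- function(ve, conc) {
  conc <- as.data.frame(conc)
  if (any(conc$concentration < 0))
    stop_input("concentrations must be non-negative")
  if (is.data.frame(ve)) {
    stopifnot(all(c("minute_index", "ve") %in% names(ve)))
    tab <- merge(ve, conc, by = "minute_index")
    skipped <- c(no_ve = sum(!(conc$minute_index %in% ve$minute_index)),
                 no_concentration =
                   sum(!(ve$minute_index %in% conc$minute_index)))
  } else {
    if (length(ve) != nrow(conc))
      stop_input("ve vector must match the exposure series length ",
                 "(or pass a data.frame keyed by minute_index)")
    tab <- data.frame(minute_index = conc$minute_index, ve = ve,
                      concentration = conc$concentration)
    skipped <- c(no_ve = 0L, no_concentration = 0L)
  }
  if (any(is.na(tab$ve) | tab$ve <= 0))
    stop_input("VE must be positive for every covered minute")
  tab$incremental_dose <- tab$concentration * tab$ve * 1e-3
  structure(list(
    total_dose = sum(tab$incremental_dose),
    per_minute = tab[order(tab$minute_index),
                     c("minute_index", "ve", "concentration",
                       "incremental_dose")],
    minutes_covered = nrow(tab),
    minutes_skipped = skipped
  ), class = "dose_result")
}

#' @export
print.dose_result <- function(x, ...) {
  cat("<dose_result> total inhaled dose = ", signif(x$total_dose, 4),
      " ug over ", x$minutes_covered, " min", sep = "")
  if (sum(x$minutes_skipped))
    cat(" (skipped: ", paste(names(x$minutes_skipped), x$minutes_skipped,
                             sep = "=", collapse = ", "), ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Predict per-minute VE for one subject and integrate inhaled dose
#'
#' Convenience wrapper chaining model prediction, minute alignment and
#' dose integration for a single subject's session.
#'
#' @param records Per-minute records for one subject (`minute_index`,
#'   `hr`, optional `fb`).
#' @param subject One-row [subject_table()].
#' @param conc An [exposure_series()].
#' @param model A [power_function_model()]; default [model_d2()].
#' @param fvc_policy,reference_table FVC resolution, see [resolve_fvc()].
#' @return A `dose_result` whose `per_minute` table also carries the
#'   alignment's skip counts.
#' @export
estimate_dose <- function(records, subject, conc, model = model_d2(),
                          fvc_policy = "prefer_measured",
                          reference_table = gli_reference_table()) {
  subject <- as.data.frame(subject)
  stopifnot(nrow(subject) == 1L)
  need_fb <- "fb" %in% model$required
  aligned <- align_to_minute_grid(
    records[c("minute_index", "hr")], conc,
    fb = if (!is.null(records$fb)) records[c("minute_index", "fb")],
    require_fb = need_fb
  )
  fvc <- if ("fvc" %in% model$required) {
    pred <- if (fvc_policy != "measured_only" && is.na(subject$measured_fvc))
      predict_fvc(subject, reference_table) else NA_real_
    resolve_fvc(subject$measured_fvc, pred, fvc_policy)$fvc
  } else NULL
  ve <- predict_ve(model, hr = aligned$hr,
                   fb = if (need_fb) aligned$fb else NULL,
                   age = subject$age, sex = subject$sex_code, fvc = fvc)
  res <- integrate_dose(data.frame(minute_index = aligned$minute_index,
                                   ve = ve), conc)
  res$minutes_skipped <- c(res$minutes_skipped, attr(aligned, "skipped"))
  res
}
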