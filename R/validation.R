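# Model validation: signed percent error, subject-grouped k-fold
# cross-validation, published-model benchmarking and stratified
# performance reports.

#' Signed percent error of a prediction
#'
#' `(prediction - observation) / observation * 100`.
#'
#' @param prediction,observation VE in L/min; `observation` must be > 0.
#' @return Numeric vector of percent errors.
#' @export
percent_error <- function(prediction, observation) {
  if (any(is.na(observation) | observation <= 0))
    stop_input("observation must be strictly positive")
  (prediction - observation) / observation * 100
}

#' Summarize a distribution of percent errors
#'
#' Median and inter-quartile range (Q3 - Q1) use linear-interpolation
#' quantiles (R's default, `type = 7`); the rule is configurable because
#' printed IQRs depend on it.  `frac_over`/`frac_under` split predictions
#' into over- and under-estimates (an exact zero counts as over, so the
#' two always sum to 100%); `frac_over25`/`frac_under25` count errors of
#' at least +/-25%.
#'
#' @param errors Numeric vector of signed percent errors (non-empty).
#' @param quantile_type Passed to [stats::quantile()].
#' @return One-row `data.frame` of class `error_summary` with columns
#'   `median_pe`, `iqr_pe`, `frac_over`, `frac_under`, `frac_over25`,
#'   `frac_under25`, `n` (fractions in percent).
#' @examples
#' summarize_errors(c(-10, 0, 10))  # median 0, IQR 10
#' @export
summarize_errors <- function(errors, quantile_type = 7) {
  errors <- errors[!is.na(errors)]
  if (!length(errors)) stop_input("no percent errors to summarize")
  q <- stats::quantile(errors, c(0.25, 0.5, 0.75), type = quantile_type,
                       names = FALSE)
  out <- data.frame(
    median_pe = q[2], iqr_pe = q[3] - q[1],
    frac_over = 100 * mean(errors >= 0),
    frac_under = 100 * mean(errors < 0),
    frac_over25 = 100 * mean(errors >= 25),
    frac_under25 = 100 * mean(errors <= -25),
    n = length(errors)
  )
  class(out) <- c("error_summary", "data.frame")
  out
}

#' Assign subjects to cross-validation folds
#'
#' Random mode partitions subjects (never records — records of one subject
#' always share a fold, preventing leakage) into `k` folds whose sizes
#' differ by at most one.  Group mode (`group_by`) makes one fold per
#' distinct value of a subject column (study, sex, ...), ignoring `k`:
#' leave-one-group-out validation.
#'
#' @param subjects A [subject_table()], `physio_dataset`, or character
#'   vector of subject ids.
#' @param k Number of folds (random mode), >= 2.
#' @param seed Integer seed for the random partition (RNG state is
#'   restored afterwards).
#' @param group_by Optional subject column name for group mode.
#' @return Object of class `fold_assignment`: `assignment`
#'   (`data.frame(subject_id, fold)`), `k`, `seed`, `group_by`, and
#'   `fold_labels` in group mode.
#' @export
make_folds <- function(subjects, k = 10, seed = 1, group_by = NULL) {
  if (inherits(subjects, "physio_dataset")) subjects <- subjects$subjects
  sdf <- if (is.character(subjects))
    data.frame(subject_id = subjects, stringsAsFactors = FALSE)
    else as.data.frame(subjects)
  ids <- sdf$subject_id
  if (anyDuplicated(ids)) stop_input("duplicate subject ids")
  n <- length(ids)
  if (!is.null(group_by)) {
    if (!group_by %in% names(sdf))
      stop_input("no subject column '", group_by, "' to group by")
    g <- factor(sdf[[group_by]])
    assignment <- data.frame(subject_id = ids,
                             fold = as.integer(g),
                             stringsAsFactors = FALSE)
    return(structure(list(assignment = assignment, k = nlevels(g),
                          seed = NA_integer_, group_by = group_by,
                          fold_labels = levels(g)),
                     class = "fold_assignment"))
  }
  if (k < 2) stop_input("k must be at least 2")
  if (k > n) stop_input("k (", k, ") exceeds number of subjects (", n, ")")
  fold <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  structure(list(
    assignment = data.frame(subject_id = ids, fold = fold,
                            stringsAsFactors = FALSE),
    k = k, seed = seed, group_by = NULL
  ), class = "fold_assignment")
}

#' Subject-grouped cross-validation of a log-log mixed model
#'
#' For every fold: fits the model on the training subjects
#' ([fit_loglog_lmm()]), exports the fixed effects ([as_power_model()])
#' and predicts the held-out subjects' records at the population level
#' (random effects zero — no subject-specific effect exists for a subject
#' the model never saw).  All validation-set predictions are pooled and
#' summarized.
#'
#' @param ds A [physio_dataset()] with observed VE.
#' @param formula A [ve_formula()].
#' @param folds A [make_folds()] assignment; defaults to 10 random folds
#'   with `seed`.
#' @param fvc_policy,reference_table As in [fit_loglog_lmm()].
#' @param seed Used only when `folds` is `NULL`.
#' @return Object of class `cv_report`: `predictions` (per-record
#'   observed/predicted/fold/percent_error), `summary` (pooled
#'   [summarize_errors()]), `folds`, `fits` (per-fold coefficient tables).
#' @export
cross_validate <- function(ds, formula = d2_formula(), folds = NULL,
                           fvc_policy = "prefer_measured",
                           reference_table = gli_reference_table(),
                           seed = 1) {
  stopifnot(inherits(ds, "physio_dataset"))
  if (is.null(folds)) folds <- make_folds(ds$subjects, k = 10, seed = seed)
  stopifnot(inherits(folds, "fold_assignment"))
  asg <- folds$assignment
  missing_subj <- setdiff(ds$subjects$subject_id, asg$subject_id)
  if (length(missing_subj))
    stop_input(length(missing_subj), " subject(s) have no fold assignment")

  preds <- vector("list", folds$k)
  fits <- vector("list", folds$k)
  for (f in seq_len(folds$k)) {
    val_ids <- asg$subject_id[asg$fold == f]
    train <- subset_dataset(ds, setdiff(ds$subjects$subject_id, val_ids))
    fit <- tryCatch(
      fit_loglog_lmm(train, formula, fvc_policy, reference_table),
      error = function(e) stop_input("training fit failed in fold ", f,
                                     ": ", conditionMessage(e))
    )
    fits[[f]] <- fit$coefficients
    pm <- as_power_model(fit, paste0("fold", f))
    val <- subset_dataset(ds, val_ids)
    pv <- predict_dataset(val, pm, fvc_policy, reference_table)
    pv <- pv[!is.na(pv$ve_observed), , drop = FALSE]
    if (nrow(pv)) {
      preds[[f]] <- data.frame(
        subject_id = pv$subject_id, minute_index = pv$minute_index,
        fold = f, observed = pv$ve_observed, predicted = pv$ve_pred,
        percent_error = percent_error(pv$ve_pred, pv$ve_observed),
        stringsAsFactors = FALSE
      )
    }
  }
  predictions <- do.call(rbind, preds)
  structure(list(
    predictions = predictions,
    summary = summarize_errors(predictions$percent_error),
    folds = folds, formula = formula, fits = fits
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  s <- x$summary
  cat("<cv_report> ", x$folds$k, "-fold subject-grouped cross-validation\n",
      sep = "")
  cat(sprintf(
    "  percent error median(IQR) = %.3g(%.3g)%%, over(under) = %.0f(%.0f)%%, n = %d\n",
    s$median_pe, s$iqr_pe, s$frac_over, s$frac_under, s$n))
  invisible(x)
}

# Subset a physio_dataset to a set of subjects (keeps provenance).
subset_dataset <- function(ds, subject_ids) {
  physio_dataset(
    ds$records[ds$records$subject_id %in% subject_ids, , drop = FALSE],
    {
      s <- ds$subjects[ds$subjects$subject_id %in% subject_ids, ,
                       drop = FALSE]
      class(s) <- c("subject_table", "data.frame"); s
    },
    provenance = ds$provenance
  )
}

#' Benchmark fixed published models against observed VE
#'
#' Published comparison models have fixed coefficients, so no training or
#' fold structure is needed: each model is evaluated once on every record
#' that carries its required predictors and an observed VE, and the
#' percent-error distribution is summarized.  The result is identical for
#' any fold assignment.
#'
#' @param ds A [physio_dataset()] with observed VE.
#' @param models Character vector of ids from [legacy_models()].
#' @param records `"required"` (default) evaluates each model on the
#'   records carrying its own required channels (a breath-frequency model
#'   uses only records with fB); `"fb_subset"` restricts every model to
#'   records that have fB, making all models comparable on one common
#'   subset.
#' @return `data.frame`: one row per model with its [summarize_errors()]
#'   columns.
#' @export
benchmark_legacy <- function(ds, models = names(legacy_models()),
                             records = c("required", "fb_subset")) {
  records <- match.arg(records)
  reg <- legacy_models()
  bad <- setdiff(models, names(reg))
  if (length(bad)) stop_input("unknown model id(s): ",
                              paste(bad, collapse = ", "))
  ds_use <- ds
  if (records == "fb_subset") {
    keep <- !is.na(ds$records$fb)
    ds_use <- physio_dataset(ds$records[keep, , drop = FALSE], ds$subjects,
                             ds$provenance)
  }
  rows <- lapply(models, function(id) {
    pv <- predict_dataset(ds_use, reg[[id]])
    pv <- pv[!is.na(pv$ve_observed) & !is.na(pv$ve_pred) & pv$ve_pred > 0,
             , drop = FALSE]
    cbind(data.frame(model = id),
          summarize_errors(percent_error(pv$ve_pred, pv$ve_observed)))
  })
  do.call(rbind, rows)
}

#' Stratify cross-validation performance by lung-function status
#'
#' Splits the pooled validation predictions by each subject's
#' measured-vs-predicted FVC status (low < 85% predicted, normal 85-115%,
#' high > 115%, unmeasured) and reports an [summarize_errors()] row per
#' stratum plus an all-subjects row.  `n` counts records, not subjects.
#' Empty strata are omitted.
#'
#' @param report A `cv_report`.
#' @param status `data.frame(subject_id, status)`, e.g. built with
#'   [classify_fvc_status()].
#' @return `data.frame` with a `stratum` column and summary columns.
#' @export
stratify_report <- function(report, status) {
  stopifnot(inherits(report, "cv_report"))
  status <- as.data.frame(status)
  if (!all(c("subject_id", "status") %in% names(status)))
    stop_input("status needs columns subject_id and status")
  pr <- merge(report$predictions, status[c("subject_id", "status")],
              by = "subject_id")
  if (nrow(pr) < nrow(report$predictions))
    stop_input("every predicted subject must be classified")
  rows <- list(cbind(data.frame(stratum = "all"),
                     summarize_errors(pr$percent_error)))
  for (st in levels(factor(pr$status))) {
    e <- pr$percent_error[pr$status == st]
    if (length(e))
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(stratum = st), summarize_errors(e))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
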