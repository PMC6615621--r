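# One-call pooled analysis: ingest -> cohort summary -> mixed-model fits
# -> subject-grouped cross-validation -> published-model benchmark ->
# lung-function stratification.  This is the pipeline to run on a pooled
# per-minute deposit (one flat delimited file with subject traits
# repeated per row, or separate record/subject files).

#' Run the full pooled minute-ventilation analysis
#'
#' @param ds A [physio_dataset()] (e.g. from [ingest_dataset()]).
#' @param reference_table Reference table for predicted FVC; the reported
#'   fits use predicted FVC for every subject (`fvc_policy
#'   = "predicted_only"` by default) so that subjects without spirometry
#'   are usable, with measured FVC kept for stratification.
#' @param k,seed Cross-validation folds and fold seed.
#' @param fvc_policy FVC policy for fitting and CV.
#' @param models Which of the two built-in formulas to run:
#'   `"d1"`, `"d2"` or both.
#' @param benchmark Also evaluate the published comparison models.
#' @return List of class `pooled_analysis`: `summary`
#'   ([summarize_dataset()]), per-model `fits`, `cv` reports,
#'   `stratified` (D2-style lung-function strata when measured FVC
#'   exists), and `benchmark`.
#' @export
run_pooled_analysis <- function(ds,
                                reference_table = gli_reference_table(),
                                k = 10, seed = 1,
                                fvc_policy = "predicted_only",
                                models = c("d1", "d2"),
                                benchmark = TRUE) {
  stopifnot(inherits(ds, "physio_dataset"))
  models <- match.arg(models, several.ok = TRUE)
  formulas <- list(d1 = d1_formula(), d2 = d2_formula())[models]

  fits <- lapply(formulas, function(f)
    fit_loglog_lmm(ds, f, fvc_policy, reference_table))
  cv <- lapply(formulas, function(f)
    cross_validate(ds, f, make_folds(ds$subjects, k = k, seed = seed),
                   fvc_policy, reference_table))

  stratified <- NULL
  if (any(!is.na(ds$subjects$measured_fvc)) && "d2" %in% models) {
    pred <- predict_fvc(ds$subjects, reference_table)
    cls <- classify_fvc_status(ds$subjects$measured_fvc, pred)
    status <- data.frame(subject_id = ds$subjects$subject_id,
                         status = cls$status)
    stratified <- stratify_report(cv$d2, status)
  }
  bench <- if (benchmark) benchmark_legacy(ds) else NULL

  structure(list(summary = summarize_dataset(ds), fits = fits, cv = cv,
                 stratified = stratified, benchmark = bench,
                 k = k, seed = seed, fvc_policy = fvc_policy),
            class = "pooled_analysis")
}

#' Reproduce the pooled analysis from deposited files
#'
#' Thin wrapper: [ingest_dataset()] then [run_pooled_analysis()].  Point
#' it at a pooled per-minute deposit (with a column map matching its
#' layout) and a reference coefficient table directory.
#'
#' @param records_file Delimited per-minute file.
#' @param subjects_file Optional separate subject file.
#' @param column_map See [default_column_map()].
#' @param reference_dir Directory for [read_reference_table()]; `NULL`
#'   uses the packaged synthetic table.
#' @param ... Passed to [run_pooled_analysis()].
#' @return A `pooled_analysis`.
#' @export
reproduce_pooled_analysis <- function(records_file, subjects_file = NULL,
                                      column_map = default_column_map(),
                                      reference_dir = NULL, ...) {
  ds <- ingest_dataset(records_file, subjects_file, column_map)
  tab <- if (is.null(reference_dir)) gli_reference_table()
    else read_reference_table(reference_dir)
  run_pooled_analysis(ds, reference_table = tab, ...)
}

#' @export
print.pooled_analysis <- function(x, ...) {
  cat("<pooled_analysis>\n")
  print(x$summary)
  for (m in names(x$fits)) {
    cat("\n-- model ", m, " --\n", sep = "")
    print(x$fits[[m]])
    print(x$cv[[m]])
  }
  if (!is.null(x$stratified)) {
    cat("\n-- performance by lung-function status (model d2) --\n")
    print(x$stratified, row.names = FALSE)
  }
  if (!is.null(x$benchmark)) {
    cat("\n-- published comparison models --\n")
    print(x$benchmark, row.names = FALSE)
  }
  invisible(x)
}
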