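# Spirometry reference equations: GLI-style predicted FVC/FEV1 from
# height, age, sex and reference group, plus measured-vs-predicted
# classification into the low / normal / high strata used for performance
# stratification.

#' Reference (ethnic) groups for spirometry equations
#' @export
gli_groups <- c("Caucasian", "AfricanAmerican", "NorthEastAsian",
                "SouthEastAsian", "Other")

#' Map a free-text ethnicity label to a spirometry reference group
#'
#' Implements the assignment rules used for multi-country pooled cohorts:
#' white subjects are assigned to Caucasian; subjects of African (American)
#' ancestry to AfricanAmerican; "Asian" without North/South sub-region
#' information and "Hispanic" without further ancestry information cannot
#' be placed in a specific group and fall to Other, as do empty or
#' unrecognized labels (with a warning).  The function is total: it never
#' errors.
#'
#' @param ethnicity_label Character vector of free-text labels.
#' @param country Character vector (recycled) of study countries; retained
#'   for future country-specific rules and documentation of provenance.
#' @return Character vector of [gli_groups] values.
#' @examples
#' map_to_gli_group("Caucasian", "Portugal")  # "Caucasian"
#' map_to_gli_group("Hispanic", "US")         # "Other"
#' @export
map_to_gli_group <- function(ethnicity_label, country = "") {
  n <- max(length(ethnicity_label), length(country))
  lab <- tolower(trimws(rep_len(as.character(ethnicity_label), n)))
  lab[is.na(lab)] <- ""
  out <- rep("Other", n)
  out[grepl("caucasian|white|european", lab)] <- "Caucasian"
  out[grepl("african|black", lab)] <- "AfricanAmerican"
  out[grepl("north.?east.?asian|korean|japanese|chinese", lab)] <-
    "NorthEastAsian"
  out[grepl("south.?east.?asian|thai|vietnamese|filipino|malay|indonesian",
            lab)] <- "SouthEastAsian"
  # bare "asian" and "hispanic"/"latino" carry no usable sub-region: Other
  unknown <- !nzchar(lab)
  if (any(unknown))
    warning(sum(unknown), " empty/unknown ethnicity label(s) assigned to ",
            "'Other'", call. = FALSE)
  out
}

#' Load a reference-equation coefficient table
#'
#' The on-disk format is two CSVs plus a JSON manifest:
#' `coefficients.csv` with columns `(sex, group, outcome, a0, a1, a2)` and
#' `spline.csv` with `(sex, group, outcome, age, spline_value)`, where the
#' predicted value is
#' `exp(a0 + a1*log(height_cm) + a2*log(age) + spline(age))` in liters and
#' the age-varying spline contribution is linearly interpolated between
#' tabulated ages.  `sex` is coded 1/2 as elsewhere; `outcome` is `FVC` or
#' `FEV1`.
#'
#' @param dir Directory containing the three files.
#' @return Object of class `reference_table`.
#' @seealso [gli_reference_table()] for the packaged table.
#' @export
read_reference_table <- function(dir) {
  cf <- file.path(dir, "coefficients.csv")
  sf <- file.path(dir, "spline.csv")
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(cf)) stop_input("no coefficients.csv under ", dir)
  coef <- utils::read.csv(cf, stringsAsFactors = FALSE)
  need <- c("sex", "group", "outcome", "a0", "a1", "a2")
  if (!all(need %in% names(coef)))
    stop_input("coefficients.csv must have columns ",
               paste(need, collapse = ", "))
  spline <- if (file.exists(sf)) utils::read.csv(sf, stringsAsFactors = FALSE)
    else data.frame(sex = integer(), group = character(),
                    outcome = character(), age = numeric(),
                    spline_value = numeric())
  manifest <- if (file.exists(mf)) jsonlite::read_json(mf) else list()
  structure(list(coefficients = coef, spline = spline, manifest = manifest),
            class = "reference_table")
}

#' Packaged synthetic reference table
#'
#' Returns the coefficient table shipped with the package.  The table uses
#' the GLI functional form and covers all five reference groups, both
#' sexes and both outcomes over ages 4-90, but its numeric values are
#' synthetic: they were calibrated to give physiologically sensible adult
#' lung volumes (FVC roughly 2-7 L, FEV1 = 0.8 FVC), not copied from any
#' published equation set.  It makes the pipeline runnable and testable
#' offline; for production estimates load a real published table with
#' [read_reference_table()] or supply measured FVC.
#'
#' @return A `reference_table`.
#' @export
gli_reference_table <- function() {
  read_reference_table(system.file("extdata", "gli_synthetic",
                                   package = "ventdose", mustWork = TRUE))
}

#' Construct a minimal in-memory reference table
#'
#' Convenience constructor for tests and examples: one coefficient row
#' replicated over all sexes and groups, optional tabulated spline.
#'
#' @param a0,a1,a2 Coefficients of the log-linear part.
#' @param spline Optional `data.frame(age, spline_value)`.
#' @param outcome Outcome the row describes.
#' @return A `reference_table`.
#' @export
toy_reference_table <- function(a0, a1, a2, spline = NULL,
                                outcome = "FVC") {
  grid <- expand.grid(sex = 1:2, group = gli_groups,
                      stringsAsFactors = FALSE)
  coef <- data.frame(grid, outcome = outcome, a0 = a0, a1 = a1, a2 = a2)
  sp <- if (is.null(spline)) {
    data.frame(sex = integer(), group = character(), outcome = character(),
               age = numeric(), spline_value = numeric())
  } else {
    do.call(rbind, lapply(seq_len(nrow(grid)), function(i)
      data.frame(sex = grid$sex[i], group = grid$group[i],
                 outcome = outcome, age = spline$age,
                 spline_value = spline$spline_value)))
  }
  structure(list(coefficients = coef, spline = sp,
                 manifest = list(source = "toy", version = "0")),
            class = "reference_table")
}

lookup_coef <- function(table, sex, group, outcome) {
  cf <- table$coefficients
  row <- cf[cf$sex == sex & cf$group == group & cf$outcome == outcome, ]
  if (nrow(row) == 0L)
    row <- cf[cf$sex == sex & cf$group == "Other" & cf$outcome == outcome, ]
  if (nrow(row) == 0L)
    stop_input("reference table has no row for sex=", sex, ", group=",
               group, ", outcome=", outcome)
  row[1L, ]
}

spline_at <- function(table, sex, group, outcome, age) {
  sp <- table$spline
  sp <- sp[sp$sex == sex & sp$group == group & sp$outcome == outcome, ]
  if (nrow(sp) == 0L) return(0)
  if (age < min(sp$age) || age > max(sp$age))
    warning("age ", age, " outside tabulated spline range [",
            min(sp$age), ", ", max(sp$age), "]; extrapolating flat",
            call. = FALSE)
  stats::approx(sp$age, sp$spline_value, xout = age, rule = 2)$y
}

#' Predict lung function from demographics
#'
#' Evaluates `exp(a0 + a1*log(height) + a2*log(age) + spline(age))` for
#' each subject, with coefficients selected by (sex, reference group,
#' outcome).  Subjects without a `gli_group` column (or with `NA`) are
#' assigned via [map_to_gli_group()] from their ethnicity label.
#'
#' @param subjects A [subject_table()] or data.frame with `age`,
#'   `sex_code`, `height` (cm) and optionally `gli_group`/`ethnicity`.
#' @param table A `reference_table`.
#' @param outcome `"FVC"` (default) or `"FEV1"`.
#' @return Numeric vector of predicted volumes in liters (strictly
#'   positive); `NA` with a warning would violate the contract, so missing
#'   height or age raise an error instead.
#' @examples
#' tab <- toy_reference_table(-10, 2, 0.1)
#' predict_fvc(data.frame(age = 30, sex_code = 1, height = 170), tab)
#' @export
predict_lung_function <- function(subjects, table,
                                  outcome = c("FVC", "FEV1")) {
  outcome <- match.arg(outcome)
  stopifnot(inherits(table, "reference_table"))
  s <- as.data.frame(subjects)
  if (any(is.na(s$height)) || any(is.na(s$age)))
    stop_input("height and age are required to predict ", outcome,
               " (missing for ",
               sum(is.na(s$height) | is.na(s$age)), " subject(s))")
  if (any(s$height <= 0) || any(s$age <= 0))
    stop_input("height and age must be positive")
  group <- if (!is.null(s$gli_group) && !all(is.na(s$gli_group))) {
    g <- as.character(s$gli_group)
    g[is.na(g)] <- suppressWarnings(
      map_to_gli_group(s$ethnicity[is.na(g)] %||% "", ""))
    g
  } else {
    suppressWarnings(map_to_gli_group(s$ethnicity %||% rep("", nrow(s)),
                                      s$country %||% ""))
  }
  vapply(seq_len(nrow(s)), function(i) {
    cf <- lookup_coef(table, s$sex_code[i], group[i], outcome)
    sp <- spline_at(table, cf$sex, cf$group, outcome, s$age[i])
    exp(cf$a0 + cf$a1 * log(s$height[i]) + cf$a2 * log(s$age[i]) + sp)
  }, numeric(1))
}

#' @rdname predict_lung_function
#' @export
predict_fvc <- function(subjects, table) {
  predict_lung_function(subjects, table, "FVC")
}

#' @rdname predict_lung_function
#' @export
predict_fev1 <- function(subjects, table) {
  predict_lung_function(subjects, table, "FEV1")
}

#' Classify measured FVC against its predicted value
#'
#' Percent predicted is `measured / predicted * 100`.  Status is `low`
#' below 85% predicted, `high` above 115%, `normal` in between (both
#' boundaries inclusive in `normal`), and `unmeasured` when no measurement
#' exists — the stratification used when reporting model performance by
#' lung-function status.
#'
#' @param measured Measured FVC in liters, `NA` for unmeasured.
#' @param predicted Predicted FVC in liters (> 0).
#' @return `data.frame` with `predicted_fvc`, `percent_predicted` (`NA`
#'   when unmeasured) and `status` (factor low/normal/high/unmeasured).
#' @examples
#' classify_fvc_status(4, 5)   # 80%, low
#' classify_fvc_status(6, 5)   # 120%, high
#' @export
classify_fvc_status <- function(measured, predicted) {
  n <- max(length(measured), length(predicted))
  measured <- rep_len(as.numeric(measured), n)
  predicted <- rep_len(as.numeric(predicted), n)
  if (any(is.na(predicted) | predicted <= 0))
    stop_input("predicted FVC must be positive")
  if (any(!is.na(measured) & measured <= 0))
    stop_input("measured FVC must be positive when present")
  pct <- 100 * measured / predicted
  status <- ifelse(is.na(measured), "unmeasured",
            ifelse(pct < 85, "low", ifelse(pct > 115, "high", "normal")))
  data.frame(predicted_fvc = predicted, percent_predicted = pct,
             status = factor(status, levels = c("low", "normal", "high",
                                                "unmeasured")))
}
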