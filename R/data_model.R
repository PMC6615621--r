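# Domain containers: subject tables, per-minute physiological records and
# the pooled dataset object that every downstream module consumes.

#' Construct a subject table
#'
#' Builds and validates a table of subject-level covariates.  One row per
#' subject.  `sex_code` follows the numeric convention used throughout the
#' package: 1 for males, 2 for females, so that the log-transformed code can
#' enter regression models directly.
#'
#' @param subject_id Character vector of unique subject identifiers.
#' @param age Age in years (> 0).
#' @param sex_code Integer 1 (male) or 2 (female).
#' @param height Standing height in cm (optional, `NA` allowed).
#' @param weight Body mass in kg (optional).
#' @param ethnicity Free-text race/ethnicity label (optional).
#' @param country Country of the contributing study (optional); used with
#'   `ethnicity` when assigning spirometry reference groups.
#' @param study_id Identifier of the contributing study (optional).
#' @param measured_fvc Measured forced vital capacity in liters (optional).
#' @param measured_fev1 Measured FEV1 in liters (optional).  A value larger
#'   than `measured_fvc` is physiologically impossible and triggers a
#'   warning (the row is kept; spirometry rounding can produce small
#'   violations).
#' @return A `data.frame` of class `subject_table`.
#' @examples
#' subject_table("A", age = 30, sex_code = 1, height = 175)
#' @export
subject_table <- function(subject_id, age, sex_code,
                          height = NA_real_, weight = NA_real_,
                          ethnicity = NA_character_, country = NA_character_,
                          study_id = NA_character_,
                          measured_fvc = NA_real_, measured_fev1 = NA_real_) {
  df <- data.frame(
    subject_id = as.character(subject_id),
    age = as.numeric(age),
    sex_code = as.integer(sex_code),
    height = as.numeric(height),
    weight = as.numeric(weight),
    ethnicity = as.character(ethnicity),
    country = as.character(country),
    study_id = as.character(study_id),
    measured_fvc = as.numeric(measured_fvc),
    measured_fev1 = as.numeric(measured_fev1),
    stringsAsFactors = FALSE
  )
  validate_subject_table(df)
}

validate_subject_table <- function(df) {
  if (anyDuplicated(df$subject_id))
    stop_input("duplicate subject_id in subject table")
  if (any(!is.na(df$age) & df$age <= 0))
    stop_input("age must be positive")
  if (any(is.na(df$age)))
    stop_input("age is required for every subject")
  if (!all(df$sex_code %in% c(1L, 2L)))
    stop_input("sex_code must be 1 (male) or 2 (female)")
  if (any(!is.na(df$measured_fvc) & df$measured_fvc <= 0))
    stop_input("measured_fvc must be positive when present")
  both <- !is.na(df$measured_fvc) & !is.na(df$measured_fev1)
  if (any(both & df$measured_fev1 > df$measured_fvc))
    warning("measured_fev1 exceeds measured_fvc for ",
            sum(both & df$measured_fev1 > df$measured_fvc),
            " subject(s); kept but physiologically implausible",
            call. = FALSE)
  class(df) <- c("subject_table", "data.frame")
  df
}

#' Construct a pooled physiological dataset
#'
#' Binds per-minute physiological records to a subject table and enforces
#' referential integrity: every record must resolve to exactly one subject
#' and no (subject, session, minute) may appear twice.
#'
#' @param records `data.frame` with columns `subject_id`, `minute_index`
#'   (integer minute within session), `hr` (beats/min, > 0), and optionally
#'   `fb` (breaths/min, > 0 when present), `ve_observed` (L/min, > 0 when
#'   present), `activity` and `session`.
#' @param subjects A [subject_table()].
#' @param provenance Optional list describing where the data came from
#'   (source path, ingest log, drop counts).
#' @return An object of class `physio_dataset` with elements `records`,
#'   `subjects` and `provenance`.
#' @export
physio_dataset <- function(records, subjects, provenance = list()) {
  subjects <- if (inherits(subjects, "subject_table")) subjects else
    validate_subject_table(as.data.frame(subjects))
  records <- as.data.frame(records)
  for (col in c("subject_id", "minute_index", "hr"))
    if (is.null(records[[col]]))
      stop_input("records must contain column '", col, "'")
  if (is.null(records$fb)) records$fb <- NA_real_
  if (is.null(records$ve_observed)) records$ve_observed <- NA_real_
  if (is.null(records$activity)) records$activity <- NA_character_
  if (is.null(records$session)) records$session <- 1L
  records$subject_id <- as.character(records$subject_id)
  records$minute_index <- as.integer(records$minute_index)
  records$hr <- as.numeric(records$hr)
  records$fb <- as.numeric(records$fb)
  records$ve_observed <- as.numeric(records$ve_observed)

  if (any(is.na(records$hr) | records$hr <= 0))
    stop_input("all records must have hr > 0 (use ingest_dataset() to ",
               "filter raw files)")
  if (any(!is.na(records$fb) & records$fb <= 0))
    stop_input("fb must be > 0 when present")
  if (any(!is.na(records$ve_observed) & records$ve_observed <= 0))
    stop_input("ve_observed must be > 0 when present")
  unknown <- setdiff(unique(records$subject_id), subjects$subject_id)
  if (length(unknown))
    stop_input("records reference unknown subject(s): ",
               paste(utils::head(unknown, 5), collapse = ", "))
  key <- paste(records$subject_id, records$session, records$minute_index)
  if (anyDuplicated(key))
    stop_input("duplicate (subject_id, session, minute_index) in records")

  structure(
    list(records = records, subjects = subjects, provenance = provenance),
    class = "physio_dataset"
  )
}

#' @export
print.physio_dataset <- function(x, ...) {
  cat("<physio_dataset>\n")
  cat("  subjects: ", nrow(x$subjects), "\n", sep = "")
  cat("  records:  ", nrow(x$records),
      " (", sum(!is.na(x$records$fb)), " with breath frequency, ",
      sum(!is.na(x$records$ve_observed)), " with observed VE)\n", sep = "")
  nd <- x$provenance$n_dropped
  if (length(nd))
    cat("  dropped at ingest: ",
        paste(names(nd), unlist(nd), sep = "=", collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' Default column map for delimited physiological files
#'
#' Maps the package's canonical field names to source-file column names.
#' Override entries to match an arbitrary file layout; set an entry to `NA`
#' to declare the field absent.
#'
#' @param ... Named overrides, e.g. `hr = "heart_rate"`.
#' @return Named character vector canonical field -> source column.
#' @export
default_column_map <- function(...) {
  map <- c(
    subject_id = "subject_id", minute_index = "minute_index",
    hr = "hr", fb = "fb", ve_observed = "ve_observed",
    activity = "activity", session = "session",
    age = "age", sex_code = "sex_code", height = "height",
    weight = "weight", ethnicity = "ethnicity", country = "country",
    study_id = "study_id",
    measured_fvc = "measured_fvc", measured_fev1 = "measured_fev1"
  )
  dots <- c(...)
  map[names(dots)] <- dots
  map
}

read_delim_auto <- function(path, delim = NULL) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) stop_input("empty input file: ", path)
  if (is.null(delim))
    delim <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = delim, quote = "\"",
                    stringsAsFactors = FALSE, comment.char = "",
                    check.names = FALSE, fileEncoding = "UTF-8")
}

#' Ingest delimited physiological data
#'
#' Reads per-minute records (and optionally a separate subject file) from
#' comma- or tab-delimited text, applies a column map, validates every row
#' against the record invariants and assembles a [physio_dataset()].  Rows
#' that fail validation are excluded, not fixed: the count per reason is
#' recorded in the dataset provenance and reported by
#' [summarize_dataset()].  Row order within subject is preserved.
#'
#' If `subjects_file` is `NULL`, subject covariates (age, sex, ...) are
#' taken from the record file itself: the first occurrence per subject
#' defines the profile, which matches flat pooled deposits that repeat
#' subject traits on every row.
#'
#' Drop reasons: `invalid_hr` (missing, non-positive or unparseable heart
#' rate), `invalid_fb`, `invalid_ve` (non-positive or unparseable when
#' present), `unknown_subject`, `duplicate_minute`.
#'
#' @param records_file Path to the delimited record file.
#' @param subjects_file Optional path to a delimited subject file.
#' @param column_map Named map from canonical fields to source columns; see
#'   [default_column_map()].
#' @param delim Field delimiter; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @return A `physio_dataset`; `provenance$n_dropped` holds per-reason drop
#'   counts and `provenance$rows_in` the raw row count, so that
#'   `rows_in == nrow(records) + sum(n_dropped)` always holds.
#' @export
ingest_dataset <- function(records_file, subjects_file = NULL,
                           column_map = default_column_map(),
                           delim = NULL) {
  for (field in c("subject_id", "hr"))
    if (is.na(column_map[field]) || !nzchar(column_map[field]))
      stop_input("column_map must name a source column for '", field, "'")

  raw <- read_delim_auto(records_file, delim)
  pick <- function(df, field) {
    col <- column_map[field]
    if (is.na(col) || !col %in% names(df)) NULL else df[[col]]
  }
  if (is.null(pick(raw, "subject_id")) || is.null(pick(raw, "hr")))
    stop_input("record file lacks mapped column(s): need '",
               column_map["subject_id"], "' and '", column_map["hr"], "'")

  n_in <- nrow(raw)
  rec <- data.frame(subject_id = as.character(pick(raw, "subject_id")),
                    stringsAsFactors = FALSE)
  mi <- pick(raw, "minute_index")
  rec$minute_index <- if (is.null(mi)) {
    stats::ave(seq_len(n_in), rec$subject_id, FUN = seq_along)
  } else as.integer(mi)
  hr <- parse_numeric(pick(raw, "hr"))
  fb_src <- pick(raw, "fb")
  fb <- parse_numeric(if (is.null(fb_src)) rep(NA_real_, n_in) else fb_src)
  ve_src <- pick(raw, "ve_observed")
  ve <- parse_numeric(if (is.null(ve_src)) rep(NA_real_, n_in) else ve_src)
  rec$hr <- hr$value; rec$fb <- fb$value; rec$ve_observed <- ve$value
  act <- pick(raw, "activity")
  rec$activity <- if (is.null(act)) NA_character_ else as.character(act)
  ses <- pick(raw, "session")
  rec$session <- if (is.null(ses)) 1L else as.integer(ses)

  drop_reason <- rep(NA_character_, n_in)
  mark <- function(bad, reason) {
    bad <- bad & is.na(drop_reason)
    drop_reason[bad] <<- reason
  }
  mark(is.na(rec$hr) | rec$hr <= 0 | hr$bad, "invalid_hr")
  mark(fb$bad | (!is.na(rec$fb) & rec$fb <= 0), "invalid_fb")
  mark(ve$bad | (!is.na(rec$ve_observed) & rec$ve_observed <= 0),
       "invalid_ve")

  # subject table: explicit file, or first-occurrence profile per subject
  if (!is.null(subjects_file)) {
    sraw <- read_delim_auto(subjects_file, delim)
    src <- sraw
  } else {
    src <- raw[!duplicated(rec$subject_id), , drop = FALSE]
  }
  sget <- function(field, default) {
    v <- pick(src, field)
    if (is.null(v)) rep(default, nrow(src)) else v
  }
  subjects <- subject_table(
    subject_id = as.character(sget("subject_id", NA_character_)),
    age = parse_numeric(sget("age", NA_real_))$value,
    sex_code = parse_numeric(sget("sex_code", NA_real_))$value,
    height = parse_numeric(sget("height", NA_real_))$value,
    weight = parse_numeric(sget("weight", NA_real_))$value,
    ethnicity = as.character(sget("ethnicity", NA_character_)),
    country = as.character(sget("country", NA_character_)),
    study_id = as.character(sget("study_id", NA_character_)),
    measured_fvc = parse_numeric(sget("measured_fvc", NA_real_))$value,
    measured_fev1 = parse_numeric(sget("measured_fev1", NA_real_))$value
  )
  mark(!(rec$subject_id %in% subjects$subject_id), "unknown_subject")
  # duplicates judged among surviving rows: a minute whose first copy was
  # already dropped is not itself a duplicate
  key <- paste(rec$subject_id, rec$session, rec$minute_index)
  alive <- which(is.na(drop_reason))
  dup <- alive[duplicated(key[alive])]
  drop_reason[dup] <- "duplicate_minute"

  kept <- is.na(drop_reason)
  n_dropped <- as.list(table(drop_reason[!kept]))
  if (sum(!kept))
    message("ingest: dropped ", sum(!kept), " of ", n_in, " rows (",
            paste(names(n_dropped), unlist(n_dropped), sep = "=",
                  collapse = ", "), ")")
  subjects <- subjects[subjects$subject_id %in% rec$subject_id[kept] |
                         !is.null(subjects_file), , drop = FALSE]
  class(subjects) <- c("subject_table", "data.frame")
  physio_dataset(
    rec[kept, , drop = FALSE], subjects,
    provenance = list(source = records_file, rows_in = n_in,
                      n_dropped = n_dropped)
  )
}

#' Aggregate sub-minute samples to per-minute records
#'
#' Collapses timestamped physiological samples to the one-minute grid the
#' models operate on.  A record is emitted for every calendar minute that
#' contains at least one valid heart-rate sample; each channel's per-minute
#' value is the arithmetic mean (or median via `fun`) of its in-minute
#' samples.  Minutes without any HR are omitted.  Already-per-minute input
#' passes through unchanged (idempotence).
#'
#' @param samples `data.frame` with `time_s` (seconds since an arbitrary
#'   epoch; `POSIXct` accepted) or a pre-existing `minute_index`, plus `hr`
#'   and optionally `fb`, `ve_observed`, `subject_id`.
#' @param fun Aggregation statistic, `"mean"` (default) or `"median"`.
#' @return `data.frame` of per-minute records with a 1-based
#'   `minute_index` per subject.
#' @export
aggregate_to_minutes <- function(samples, fun = c("mean", "median")) {
  fun <- match.arg(fun)
  agg <- if (fun == "mean") {
    function(x) mean(x, na.rm = TRUE)
  } else {
    function(x) stats::median(x, na.rm = TRUE)
  }
  samples <- as.data.frame(samples)
  if (nrow(samples) == 0L)
    return(data.frame(subject_id = character(), minute_index = integer(),
                      hr = numeric(), fb = numeric(),
                      ve_observed = numeric()))
  if (is.null(samples$subject_id)) samples$subject_id <- "1"
  if (!is.null(samples$time_s)) {
    t <- as.numeric(samples$time_s)
    if (is.unsorted(t)) {
      warning("timestamps unsorted; sorting", call. = FALSE)
      samples <- samples[order(samples$subject_id, t), , drop = FALSE]
      t <- as.numeric(samples$time_s)
    }
    minute <- floor(t / 60)
  } else if (!is.null(samples$minute_index)) {
    minute <- as.numeric(samples$minute_index)
  } else stop_input("samples need a 'time_s' or 'minute_index' column")

  if (is.null(samples$hr)) stop_input("samples must carry 'hr'")
  keep_min <- stats::aggregate(
    list(has_hr = !is.na(samples$hr)),
    by = list(subject_id = samples$subject_id, minute = minute),
    FUN = any
  )
  chans <- intersect(c("hr", "fb", "ve_observed"), names(samples))
  out <- stats::aggregate(
    samples[chans],
    by = list(subject_id = samples$subject_id, minute = minute),
    FUN = agg
  )
  out <- merge(out, keep_min, by = c("subject_id", "minute"))
  out <- out[out$has_hr, setdiff(names(out), "has_hr"), drop = FALSE]
  out <- out[order(out$subject_id, out$minute), , drop = FALSE]
  out$minute_index <- as.integer(
    out$minute - stats::ave(out$minute, out$subject_id, FUN = min) + 1
  )
  for (ch in setdiff(c("fb", "ve_observed"), names(out)))
    out[[ch]] <- NA_real_
  out$hr[is.nan(out$hr)] <- NA_real_
  out$fb[is.nan(out$fb)] <- NA_real_
  out$ve_observed[is.nan(out$ve_observed)] <- NA_real_
  rownames(out) <- NULL
  out[c("subject_id", "minute_index", "hr", "fb", "ve_observed")]
}

#' Summarize a dataset (cohort table + ingest accounting)
#'
#' @param ds A `physio_dataset`.
#' @return A list of class `validation_report`: record/subject counts,
#'   per-reason drop counts, mean/SD/range of demographic fields (SD is
#'   `NA` when undefined, i.e. a single subject), and sex counts as
#'   frequency and percentage.
#' @export
summarize_dataset <- function(ds) {
  stopifnot(inherits(ds, "physio_dataset"))
  if (nrow(ds$records) == 0L) stop_input("dataset has no records")
  s <- ds$subjects
  num_summary <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(c(mean = NA, sd = NA, min = NA, max = NA))
    c(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else NA_real_,
      min = min(x), max = max(x))
  }
  sex_n <- c(male = sum(s$sex_code == 1L), female = sum(s$sex_code == 2L))
  nd <- ds$provenance$n_dropped %||% list()
  structure(list(
    n_subjects = nrow(s),
    n_records = nrow(ds$records),
    n_records_with_fb = sum(!is.na(ds$records$fb)),
    n_records_with_ve = sum(!is.na(ds$records$ve_observed)),
    n_dropped = nd,
    demographic_summary = rbind(
      age = num_summary(s$age),
      height = num_summary(s$height),
      weight = num_summary(s$weight)
    ),
    sex_counts = sex_n,
    sex_percent = round(100 * sex_n / nrow(s), 1)
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cat("  subjects:", x$n_subjects,
      sprintf("(male %d [%.0f%%], female %d [%.0f%%])\n",
              x$sex_counts["male"], x$sex_percent["male"],
              x$sex_counts["female"], x$sex_percent["female"]))
  cat("  records:", x$n_records, "| with fb:", x$n_records_with_fb,
      "| with observed VE:", x$n_records_with_ve, "\n")
  if (length(x$n_dropped))
    cat("  dropped:", paste(names(x$n_dropped), unlist(x$n_dropped),
                            sep = "=", collapse = ", "), "\n")
  print(round(x$demographic_summary, 1))
  invisible(x)
}

#' Write a dataset back to delimited text
#'
#' Writes `records.csv` and `subjects.csv` in the canonical layout that
#' [ingest_dataset()] reads with the default column map, closing the
#' write/ingest round trip.
#'
#' @param ds A `physio_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "physio_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rp <- file.path(dir, "records.csv")
  sp <- file.path(dir, "subjects.csv")
  utils::write.csv(ds$records, rp, row.names = FALSE, na = "")
  utils::write.csv(as.data.frame(ds$subjects), sp, row.names = FALSE,
                   na = "")
  invisible(c(records = rp, subjects = sp))
}
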