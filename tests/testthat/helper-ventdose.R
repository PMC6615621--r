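# Shared fixtures, all built in code at test time.

# Tiny deterministic dataset: 3 subjects, hand-written records.
tiny_dataset <- function() {
  subjects <- subject_table(
    subject_id = c("A", "B", "C"),
    age = c(30, 45, 12),
    sex_code = c(1, 2, 1),
    height = c(175, 162, 150),
    weight = c(70, 60, 40),
    ethnicity = c("Caucasian", "Hispanic", "Caucasian"),
    country = c("US", "US", "Canada"),
    study_id = c("s1", "s1", "s2"),
    measured_fvc = c(5.2, NA, NA)
  )
  records <- data.frame(
    subject_id = rep(c("A", "B", "C"), each = 4),
    minute_index = rep(1:4, 3),
    hr = c(60, 80, 100, 120, 65, 85, 105, 125, 70, 90, 110, 130),
    fb = c(12, 16, 20, 24, 13, 17, 21, 25, 14, 18, 22, 26),
    ve_observed = c(8, 14, 25, 40, 7, 13, 23, 38, 9, 16, 28, 45)
  )
  physio_dataset(records, subjects)
}

# Simulated dataset small enough for fast mixed-model tests.
small_sim <- function(seed = 42, n = 30, ...) {
  simulate_dataset(simulation_config(n_subjects = n, ...), seed = seed)
}

# Write a dataset's records (with subject traits repeated per row, the
# flat pooled-deposit layout) to a temp CSV; returns the path.
write_flat_file <- function(ds, path = tempfile(fileext = ".csv")) {
  flat <- merge(ds$records, as.data.frame(ds$subjects), by = "subject_id",
                sort = FALSE)
  utils::write.csv(flat, path, row.names = FALSE, na = "")
  path
}

expect_rel_equal <- function(object, expected, tol) {
  expect_true(all(abs(object - expected) <= tol * abs(expected)),
              label = paste0(deparse(substitute(object)), " within rel tol ",
                             tol, " of ", paste(signif(expected, 8),
                                                collapse = ", ")))
}
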