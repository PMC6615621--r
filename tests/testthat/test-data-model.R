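test_that("ingest filters invalid rows, counts reasons, conserves rows", {
  f <- tempfile(fileext = ".csv")
  writeLines(c(
    "subject_id,minute_index,hr,fb,ve_observed,age,sex_code,height",
    "A,1,60,12,8,30,1,175",
    "A,2,-5,14,10,30,1,175",
    "A,3,90,18,20,30,1,175"
  ), f)
  ds <- suppressMessages(ingest_dataset(f))
  expect_equal(nrow(ds$records), 2L)
  expect_equal(ds$provenance$n_dropped$invalid_hr, 1L)
  expect_equal(ds$provenance$rows_in,
               nrow(ds$records) + sum(unlist(ds$provenance$n_dropped)))
})

test_that("ingest is deterministic and the write/ingest round trip holds", {
  ds <- tiny_dataset()
  f <- write_flat_file(ds)
  a <- suppressMessages(ingest_dataset(f))
  b <- suppressMessages(ingest_dataset(f))
  expect_identical(a$records, b$records)
  expect_identical(as.data.frame(a$subjects), as.data.frame(b$subjects))

  # canonical two-file round trip
  dir <- tempfile(); paths <- write_dataset(ds, dir)
  rt <- suppressMessages(ingest_dataset(paths["records"],
                                        paths["subjects"]))
  expect_equal(rt$records$hr, ds$records$hr)
  expect_equal(rt$records$ve_observed, ds$records$ve_observed)
  expect_equal(rt$subjects$measured_fvc, ds$subjects$measured_fvc)
})

test_that("ingest rejects missing mandatory columns and empty files", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("id,heart", "A,60"), f)
  expect_error(ingest_dataset(f), "lacks mapped column")
  expect_error(
    ingest_dataset(f, column_map = default_column_map(hr = NA)),
    "column_map")
  empty <- tempfile(fileext = ".csv"); file.create(empty)
  expect_error(ingest_dataset(empty), "empty")
})

test_that("ingest handles tab delimiters, unparseable cells and unknown subjects", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("subject_id\tminute_index\thr\tage\tsex_code",
               "A\t1\t72\t30\t1",
               "A\t2\tgarbage\t30\t1",
               "A\t2\t70\t30\t1"), f)
  ds <- suppressMessages(ingest_dataset(f))
  expect_equal(nrow(ds$records), 2L)  # garbage hr dropped
  expect_equal(ds$provenance$n_dropped$invalid_hr, 1L)

  # separate subject file lacking one record's subject
  rf <- tempfile(fileext = ".csv"); sf <- tempfile(fileext = ".csv")
  writeLines(c("subject_id,minute_index,hr", "A,1,60", "B,1,70"), rf)
  writeLines(c("subject_id,age,sex_code", "A,30,1"), sf)
  ds2 <- suppressMessages(ingest_dataset(rf, sf))
  expect_equal(nrow(ds2$records), 1L)
  expect_equal(ds2$provenance$n_dropped$unknown_subject, 1L)
})

test_that("duplicate minutes are dropped at ingest and rejected by the container", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("subject_id,minute_index,hr,age,sex_code",
               "A,1,60,30,1", "A,1,62,30,1"), f)
  ds <- suppressMessages(ingest_dataset(f))
  expect_equal(nrow(ds$records), 1L)
  expect_equal(ds$provenance$n_dropped$duplicate_minute, 1L)

  s <- subject_table("A", 30, 1)
  expect_error(
    physio_dataset(data.frame(subject_id = "A", minute_index = c(1, 1),
                              hr = c(60, 62)), s),
    "duplicate")
})

test_that("minute aggregation averages within calendar minutes", {
  s <- data.frame(time_s = c(10, 40), hr = c(60, 62))
  out <- aggregate_to_minutes(s)
  expect_equal(out$hr, 61)
  expect_equal(nrow(out), 1L)

  # 90 s of 1 Hz samples spans exactly 2 calendar minutes
  s2 <- data.frame(time_s = 0:89, hr = 70)
  expect_equal(nrow(aggregate_to_minutes(s2)), 2L)

  # a minute with breath frequency but no HR is omitted
  s3 <- data.frame(time_s = c(10, 70), hr = c(60, NA), fb = c(12, 14))
  out3 <- aggregate_to_minutes(s3)
  expect_equal(nrow(out3), 1L)
  expect_equal(out3$minute_index, 1L)

  # median aggregation by config
  s4 <- data.frame(time_s = c(1, 2, 3), hr = c(60, 61, 80))
  expect_equal(aggregate_to_minutes(s4, fun = "median")$hr, 61)
})

test_that("minute aggregation is idempotent on per-minute data and sorts input", {
  perm <- data.frame(subject_id = "A", minute_index = 1:5,
                     hr = c(60, 70, 80, 90, 100), fb = 12:16,
                     ve_observed = c(8, 10, 14, 20, 30))
  again <- aggregate_to_minutes(perm)
  expect_equal(again$hr, perm$hr)
  expect_equal(again$fb, perm$fb)
  expect_equal(again$minute_index, perm$minute_index)

  unsorted <- data.frame(time_s = c(130, 10, 70), hr = c(80, 60, 70))
  expect_warning(out <- aggregate_to_minutes(unsorted), "unsorted")
  expect_equal(out$hr, c(60, 70, 80))
})

test_that("dataset summaries report counts, demographics and sex split", {
  ds <- tiny_dataset()
  rep <- summarize_dataset(ds)
  expect_equal(rep$n_subjects, 3L)
  expect_equal(rep$n_records, 12L)
  expect_equal(rep$n_records_with_fb, 12L)
  expect_equal(unname(rep$sex_counts), c(2L, 1L))
  expect_equal(rep$demographic_summary["age", "mean"], mean(c(30, 45, 12)))

  # single subject: SD undefined, flagged as NA
  one <- physio_dataset(ds$records[ds$records$subject_id == "A", ],
                        ds$subjects[1, ])
  expect_true(is.na(summarize_dataset(one)$demographic_summary["age", "sd"]))
})

test_that("container invariants reject bad physiology and bad references", {
  s <- subject_table("A", 30, 1)
  expect_error(physio_dataset(
    data.frame(subject_id = "A", minute_index = 1, hr = -1), s), "hr")
  expect_error(physio_dataset(
    data.frame(subject_id = "Z", minute_index = 1, hr = 60), s),
    "unknown subject")
  expect_error(subject_table("A", age = -3, sex_code = 1), "age")
  expect_error(subject_table("A", age = 30, sex_code = 3), "sex_code")
  expect_warning(subject_table("A", 30, 1, measured_fvc = 4,
                               measured_fev1 = 4.5), "fev1")
})
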