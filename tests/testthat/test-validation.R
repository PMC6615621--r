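test_that("percent error is the signed relative difference in percent", {
  expect_equal(percent_error(10, 10), 0)
  expect_equal(percent_error(12.5, 10), 25)
  expect_equal(percent_error(7.5, 10), -25)
  expect_equal(percent_error(c(11, 9), c(10, 10)), c(10, -10))
  expect_error(percent_error(10, 0), "positive")
  expect_error(percent_error(10, -2), "positive")
})

test_that("error summaries use linear-interpolation quantiles and 25% tails", {
  s <- summarize_errors(c(-10, 0, 10))
  expect_equal(s$median_pe, 0)
  expect_equal(s$iqr_pe, 10)  # Q3 - Q1 = 5 - (-5) under type 7

  expect_equal(summarize_errors(c(1, 2, 3))$frac_under, 0)
  s2 <- summarize_errors(c(30, -30, 0, 0))
  expect_equal(s2$frac_over25, 25)
  expect_equal(s2$frac_under25, 25)
  # a tie at zero counts as over; over + under always 100
  expect_equal(s2$frac_over + s2$frac_under, 100)
  expect_equal(s2$frac_over, 75)
  expect_error(summarize_errors(numeric()), "no percent errors")
  # the rule is configurable
  expect_equal(summarize_errors(c(-10, 0, 10), quantile_type = 1)$iqr_pe,
               diff(quantile(c(-10, 0, 10), c(.25, .75), type = 1,
                             names = FALSE)))
})

test_that("random folds are balanced, seeded and subject-exclusive", {
  ids <- sprintf("S%03d", 1:471)
  f <- make_folds(ids, k = 10, seed = 4)
  sizes <- table(f$assignment$fold)
  expect_true(all(sizes %in% c(47, 48)))
  expect_equal(sum(sizes), 471)
  expect_equal(anyDuplicated(f$assignment$subject_id), 0L)
  # same seed reproduces, different seed differs
  expect_identical(make_folds(ids, 10, seed = 4)$assignment, f$assignment)
  expect_false(identical(make_folds(ids, 10, seed = 5)$assignment,
                         f$assignment))
  # forced one-per-fold and error cases
  expect_equal(sort(make_folds(ids[1:10], k = 10, seed = 1)$assignment$fold),
               1:10)
  expect_error(make_folds(ids[1:5], k = 10), "exceeds")
  expect_error(make_folds(ids, k = 1), "at least 2")
})

test_that("group mode builds one fold per group value", {
  subs <- data.frame(subject_id = sprintf("S%02d", 1:24),
                     study_id = rep(sprintf("study%d", 1:8), 3),
                     sex_code = rep(1:2, 12))
  f <- make_folds(subs, group_by = "study_id")
  expect_equal(f$k, 8L)
  expect_equal(length(unique(f$assignment$fold)), 8L)
  expect_equal(f$fold_labels, sprintf("study%d", 1:8))
  fs <- make_folds(subs, group_by = "sex_code")
  expect_equal(fs$k, 2L)
  expect_error(make_folds(subs, group_by = "race"), "no subject column")
})

test_that("cross-validation covers every subject once and is seed-deterministic", {
  sim <- small_sim(seed = 31, n = 20)
  folds <- make_folds(sim$dataset$subjects, k = 4, seed = 9)
  cv <- cross_validate(sim$dataset, d2_formula(), folds)
  # every eligible record predicted exactly once
  expect_equal(nrow(cv$predictions), nrow(sim$dataset$records))
  per_subj_folds <- tapply(cv$predictions$fold, cv$predictions$subject_id,
                           function(x) length(unique(x)))
  expect_true(all(per_subj_folds == 1))
  expect_gte(cv$summary$iqr_pe, 0)
  # pooled median within the range spanned by per-fold medians
  fold_med <- tapply(cv$predictions$percent_error, cv$predictions$fold,
                     median)
  expect_gte(cv$summary$median_pe, min(fold_med))
  expect_lte(cv$summary$median_pe, max(fold_med))
  # determinism given the seed
  cv2 <- cross_validate(sim$dataset, d2_formula(),
                        make_folds(sim$dataset$subjects, k = 4, seed = 9))
  expect_identical(cv$predictions, cv2$predictions)
})

test_that("noise-free data cross-validates to ~zero percent error", {
  sim <- small_sim(seed = 17, n = 16, sd_intercept = 0, sd_slope_hr = 0,
                   sd_slope_fb = 0, sd_residual = 0,
                   measured_fvc_fraction = 0)
  cv <- suppressWarnings(cross_validate(
    sim$dataset, d2_formula(),
    make_folds(sim$dataset$subjects, k = 4, seed = 2)))
  expect_lt(max(abs(cv$predictions$percent_error)), 0.5)
})

test_that("published-model benchmark is a single fixed pass", {
  sim <- small_sim(seed = 23, n = 12)
  b <- benchmark_legacy(sim$dataset, c("zuurbier", "do_vale", "mcardle"))
  expect_equal(b$model, c("zuurbier", "do_vale", "mcardle"))
  expect_true(all(b$n > 0))
  # no training: results identical however subjects are partitioned
  b2 <- benchmark_legacy(sim$dataset, c("zuurbier", "do_vale", "mcardle"))
  expect_identical(b, b2)
  # fb-subset mode restricts all models to the common record set
  ds <- sim$dataset
  ds$records$fb[1:40] <- NA
  ball <- benchmark_legacy(ds, "zuurbier", records = "required")
  bsub <- benchmark_legacy(ds, "zuurbier", records = "fb_subset")
  expect_equal(ball$n - 40L, bsub$n)
})

test_that("stratified reports partition records by lung-function status", {
  sim <- small_sim(seed = 29, n = 20, measured_fvc_fraction = 0.5)
  cv <- cross_validate(sim$dataset, d2_formula(),
                       make_folds(sim$dataset$subjects, k = 4, seed = 1))
  subs <- sim$dataset$subjects
  cls <- classify_fvc_status(subs$measured_fvc,
                             predict_fvc(subs, gli_reference_table()))
  status <- data.frame(subject_id = subs$subject_id, status = cls$status)
  tab <- stratify_report(cv, status)
  expect_equal(tab$stratum[1], "all")
  # strata partition the records: counts add up to the overall n
  expect_equal(sum(tab$n[tab$stratum != "all"]), tab$n[tab$stratum == "all"])
  # empty strata omitted
  expect_true(all(tab$n > 0))
  # unclassified subjects are an error
  expect_error(stratify_report(cv, status[-1, ]), "classified")
})
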