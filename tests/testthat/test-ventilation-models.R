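test_that("built-in power models evaluate their printed formulas", {
  # independent arithmetic path: exp/prod of powers, not sum of logs
  d1 <- exp(-9.59) * 100^2.39 * 30^0.274 * 1^-0.204 * 5^0.520
  expect_equal(predict_ve(model_d1(), hr = 100, age = 30, sex = 1,
                          fvc = 5), d1, tolerance = 1e-9)
  expect_gt(d1, 24); expect_lt(d1, 24.4)  # ~24.2 L/min

  d2 <- exp(-8.57) * 100^1.72 * 20^0.611 * 30^0.298 * 2^-0.206 * 4^0.614
  expect_equal(predict_ve(model_d2(), hr = 100, fb = 20, age = 30,
                          sex = 2, fvc = 4), d2, tolerance = 1e-9)
  expect_gt(d2, 18); expect_lt(d2, 18.5)  # ~18.2 L/min
})

test_that("sex enters only through the 1/2 code", {
  # male code 1: prediction independent of the sex exponent (1^b = 1)
  m_a <- model_d2()
  m_b <- power_function_model("alt", m_a$intercept,
                              replace(m_a$exponents, "sex", 5))
  args <- list(hr = 110, fb = 22, age = 40, fvc = 4.5)
  expect_equal(do.call(predict_ve, c(list(m_a), args, sex = 1)),
               do.call(predict_ve, c(list(m_b), args, sex = 1)))
  # female/male ratio is exactly 2^b_sex
  ratio <- do.call(predict_ve, c(list(m_a), args, sex = 2)) /
    do.call(predict_ve, c(list(m_a), args, sex = 1))
  expect_equal(ratio, 2^-0.206, tolerance = 1e-12)
})

test_that("power models demand their required predictors, strictly positive", {
  expect_error(predict_ve(model_d2(), hr = 100, age = 30, sex = 1,
                          fvc = 5), "fb")
  expect_error(predict_ve(model_d1(), hr = -10, age = 30, sex = 1,
                          fvc = 5), "positive")
  expect_error(predict_ve(model_d1(), hr = 100, age = 30, sex = 1,
                          fvc = 0), "positive")
  # predictions are always positive and monotone in HR and FVC
  hr <- seq(50, 190, by = 10)
  p <- predict_ve(model_d1(), hr = hr, age = 30, sex = 1, fvc = 5)
  expect_true(all(p > 0) && all(diff(p) > 0))
  fvc <- seq(2, 7, by = 0.5)
  p2 <- predict_ve(model_d2(), hr = 100, fb = 20, age = 30, sex = 2,
                   fvc = fvc)
  expect_true(all(diff(p2) > 0))
})

test_that("published comparison models reproduce hand evaluations", {
  expect_equal(predict_ve_legacy("zuurbier", hr = 80, sex = 1),
               exp(1.03 + 0.021 * 80), tolerance = 1e-12)
  expect_equal(predict_ve_legacy("zuurbier", hr = 80, sex = 2),
               exp(0.57 + 0.023 * 80), tolerance = 1e-12)
  expect_equal(predict_ve_legacy("ramos", hr = 90, sex = 1),
               exp(1.17 + 0.02 * 90), tolerance = 1e-12)
  expect_equal(predict_ve_legacy("ramos", hr = 90, sex = 2),
               exp(0.99 + 0.02 * 90), tolerance = 1e-12)
  expect_equal(predict_ve_legacy("cozza", hr = 100),
               exp(0.58 + 0.025 * 100), tolerance = 1e-12)
  expect_equal(predict_ve_legacy("do_vale", hr = 100),
               0.00071 * 100^2.17, tolerance = 1e-12)
  expect_equal(predict_ve_legacy("mcardle", fb = 12),
               12 * (1.8028 * log(12) - 3.8881), tolerance = 1e-12)
  expect_equal(predict_ve_legacy("greenwald2014", hr = 100, fb = 20),
               -4.247 + 0.0595 * 100 + 0.226 * 20, tolerance = 1e-12)
  # spot values
  expect_equal(predict_ve_legacy("zuurbier", hr = 80, sex = 1), 15.03,
               tolerance = 1e-3)
  expect_equal(predict_ve_legacy("mcardle", fb = 12), 7.10,
               tolerance = 1e-3)
  expect_equal(predict_ve_legacy("do_vale", hr = 100), 15.53,
               tolerance = 1e-3)
})

test_that("legacy models enforce their own predictor requirements", {
  expect_error(predict_ve_legacy("zuurbier", hr = 80), "sex")
  expect_error(predict_ve_legacy("mcardle", hr = 80), "fb")
  expect_error(predict_ve_legacy("nope", hr = 80), "unknown")
  # the linear model can go non-positive: flagged, not clamped
  v <- predict_ve_legacy("greenwald2014", hr = 40, fb = 5)
  expect_lt(v[1], 0)
  expect_equal(attr(v, "nonpositive"), 1L)
  expect_true(is.na(predict_ve_legacy("greenwald2014", hr = 40, fb = 5,
                                      clamp = TRUE)))
})

test_that("FVC resolution follows the requested policy", {
  r <- resolve_fvc(5.2, 4.8, "prefer_measured")
  expect_equal(r$fvc, 5.2)
  expect_equal(as.character(r$fvc_source), "measured")
  r2 <- resolve_fvc(NA, 4.8, "prefer_measured")
  expect_equal(r2$fvc, 4.8)
  expect_equal(as.character(r2$fvc_source), "predicted")
  expect_equal(resolve_fvc(5.2, 4.8, "predicted_only")$fvc, 4.8)
  expect_error(resolve_fvc(NA, 4.8, "measured_only"), "no FVC")
  # vectorized
  rv <- resolve_fvc(c(5, NA), c(4, 4.5))
  expect_equal(rv$fvc, c(5, 4.5))
  expect_equal(as.character(rv$fvc_source), c("measured", "predicted"))
})

test_that("dataset-level prediction resolves FVC and required channels", {
  ds <- tiny_dataset()
  out <- predict_dataset(ds, model_d2())
  expect_equal(nrow(out), 12L)
  expect_true(all(out$ve_pred > 0))
  # subject A has measured FVC, others fall back to predicted
  expect_equal(as.character(out$fvc_source[out$subject_id == "A"][1]),
               "measured")
  expect_equal(as.character(out$fvc_source[out$subject_id == "B"][1]),
               "predicted")
  # a record without fb is unusable for D2 but fine for D1
  ds2 <- ds
  ds2$records$fb[1] <- NA
  expect_equal(nrow(predict_dataset(ds2, model_d2())), 11L)
  expect_equal(nrow(predict_dataset(ds2, model_d1())), 12L)
  # legacy model through the same interface
  outz <- predict_dataset(ds, "zuurbier")
  expect_equal(outz$ve_pred,
               predict_ve_legacy("zuurbier", hr = outz$hr,
                                 sex = outz$sex_code))
})

test_that("user-defined models are first-class in the registry sense", {
  m <- power_function_model("refit", -9, c(hr = 2.2, age = 0.3,
                                           sex = -0.2, fvc = 0.5))
  expect_s3_class(m, "power_function_model")
  expect_equal(predict_ve(m, hr = 100, age = 30, sex = 1, fvc = 5),
               exp(-9) * 100^2.2 * 30^0.3 * 5^0.5, tolerance = 1e-12)
  expect_error(power_function_model("bad", 0, c(foo = 1)), "named")
})
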