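test_that("the reference subject matches its recorded measurements", {
  p <- paper_patient()
  expect_equal(p$edv, 53)
  expect_equal(p$edp, 14.3)
  expect_equal(p$esv, 24.8)
  expect_equal(p$lv_internal_diameter_ed, 4.6)
  expect_equal(p$posterior_wall_thickness_ed, 0.9)
})

test_that("the linear E/e' filling-pressure estimator evaluates correctly", {
  expect_equal(estimate_edp_nagueh(10), 14.3)
  expect_equal(estimate_edp_nagueh(20), 26.7)
  expect_equal(estimate_edp_nagueh(1e-9), 1.9, tolerance = 1e-6)
  expect_error(estimate_edp_nagueh(0), "positive")
  expect_error(estimate_edp_nagueh(-3), "positive")
})

test_that("sampled subjects are seeded-reproducible and physiological", {
  a <- sample_patient(7)
  b <- sample_patient(7)
  expect_identical(a, b)
  d <- patient_distributions()
  for (seed in 1:200) {
    s <- sample_patient(seed)
    expect_gt(s$edv, s$esv)
    expect_gt(s$edp, 0)
    expect_gt(s$posterior_wall_thickness_ed, 0)
    expect_true(s$edv >= d$edv["lo"] && s$edv <= d$edv["hi"])
  }
})

test_that("sample means track the configured distributions", {
  edv <- vapply(1:1000, function(s) sample_patient(s)$edv, numeric(1))
  d <- patient_distributions()$edv
  se <- d["sd"] / sqrt(1000)
  # truncation is mild, so the sample mean should sit close to the target
  expect_lt(abs(mean(edv) - d["mean"]), 3 * se + 0.5)
})

test_that("patient records round-trip through JSON", {
  f <- tempfile(fileext = ".json")
  write_patient(paper_patient(), f)
  p2 <- read_patient(f)
  expect_equal(p2$edv, 53)
  expect_equal(p2$edp, 14.3)
  unlink(f)
})

test_that("invalid measurement combinations are rejected", {
  expect_error(patient_measurements(edv = 50, esv = 60, edp = 10))
  expect_error(patient_measurements(edv = 50, esv = 20))  # no pressure route
})
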