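test_that("the single-point EDPVR interpolates its defining point exactly", {
  cv <- klotz_curve(53, 14.3)
  expect_equal(klotz_pressure(cv, 53), 14.3, tolerance = 1e-12)
  expect_equal(klotz_pressure(cv, cv$v0), 0)
  expect_equal(klotz_volume(cv, 14.3), 53, tolerance = 1e-12)
  expect_equal(cv$v30, 60.1, tolerance = 0.05)
  # monotone increasing above v0
  v <- seq(cv$v0, 70, length.out = 50)
  expect_true(all(diff(klotz_pressure(cv, v)) >= 0))
})

test_that("curve inversion round-trips", {
  cv <- klotz_curve(53, 14.3)
  p <- c(2, 5, 10, 14.3, 20)
  expect_equal(klotz_pressure(cv, klotz_volume(cv, p)), p, tolerance = 1e-10)
})

test_that("stiffness rescale drives the model EDV to its target", {
  mod <- tiny_model()
  pol <- rescale_stiffness_to_edv(mod, ref_patient$edp, ref_patient$edv,
                                  tol_ml = 0.1)
  expect_equal(pol$edv, 53, tolerance = 0.1 / 53)
  expect_gt(pol$scale, 0)
  # the b-type exponents are untouched by the rescale
  expect_equal(pol$params$b, mod$mp$b)
  expect_equal(pol$params$b_f, mod$mp$b_f)
})

test_that("the passive fit reaches the EDPVR within tolerance (self-recovery)", {
  mod <- tiny_model()
  cv <- klotz_curve(ref_patient$edv, ref_patient$edp)
  # perturbed start: 60% stiffer isotropic scale, softer fiber scale
  init <- material_params(a = 6.832e-4 * 1.6, a_f = 2.252e-3 * 0.6)
  fit <- fit_passive_params(mod, cv, ref_patient$edp, init = init, maxit = 0)
  expect_lt(fit$rms_frac_edv, 0.02)
  expect_equal(fit$volumes[length(fit$volumes)], 53, tolerance = 0.01)
})

test_that("contractility calibration short-circuits for a trivial target", {
  mod <- tiny_model()
  ed <- tiny_ed_state()
  cal <- calibrate_tmax_uniform(mod, ed$state, afterload_params(),
                                target_esv = ed$state$V)
  expect_equal(cal$tmax, 0)
})

test_that("ESV decreases monotonically over the contractility bracket", {
  mod <- tiny_model()
  ed <- tiny_ed_state()
  esv <- vapply(c(0.05, 0.09, 0.14), function(tm) {
    run_beat(set_tmax(mod, tm), ed$state, afterload_params(), dt = 0.02)$esv
  }, numeric(1))
  expect_true(all(diff(esv) < 0))
})

test_that("uniform contractility calibration hits the ESV target", {
  mod <- tiny_model()
  ed <- tiny_ed_state()
  target <- 0.55 * ed$state$V
  cal <- calibrate_tmax_uniform(mod, ed$state, afterload_params(),
                                target_esv = target, tol_ml = 0.2, dt = 0.02)
  expect_lt(abs(cal$beat$esv - target), 0.2)
  expect_gt(cal$tmax, 0)
})
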