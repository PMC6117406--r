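# numeric slice-integration oracle for the truncated-ellipsoid volume
slice_volume <- function(a, c_ax, zb, n = 20000) {
  z <- seq(-c_ax, zb, length.out = n + 1)
  zm <- (z[-1] + z[-(n + 1)]) / 2
  sum(pi * a^2 * pmax(1 - zm^2 / c_ax^2, 0) * diff(z))
}

test_that("analytic truncated-ellipsoid volume matches slice integration", {
  for (par in list(c(2.3, 3.05, 1.22), c(1.8, 2.4, 0.98), c(3, 3, 0))) {
    expect_equal(trunc_ellipsoid_volume(par[1], par[2], par[3]),
                 slice_volume(par[1], par[2], par[3]),
                 tolerance = 1e-3 / 100)   # 0.001% with 2e4 slices
  }
})

test_that("the unloading regression evaluates and validates", {
  expect_equal(klotz_unloaded_volume(53, 14.3), 27.2526, tolerance = 1e-6)
  expect_equal(klotz_unloaded_volume(80, 0), 0.6 * 80)
  expect_equal(klotz_unloaded_volume(100, 10), 54.0)
  expect_error(klotz_unloaded_volume(53, 100))
  expect_error(klotz_unloaded_volume(53, -1))
})

test_that("ED surfaces honor the echo measurements", {
  g <- build_ed_surfaces(ref_patient)
  expect_equal(g$cavity_volume, 53, tolerance = 0.005)
  expect_equal(2 * g$endo_semi_axis_short, 4.6)
  expect_equal(g$epi_semi_axis_short - g$endo_semi_axis_short, 0.9)
  expect_lt(g$truncation_height, g$endo_semi_axis_long)
  expect_gt(g$wall_volume, 0)
})

test_that("geometry scales cubically with the linear measurements", {
  g1 <- build_ed_surfaces(ref_patient)
  p2 <- patient_measurements(edv = 53 * 8, esv = 24.8 * 8, edp = 14.3,
                             lv_internal_diameter_ed = 9.2,
                             posterior_wall_thickness_ed = 1.8,
                             septal_wall_thickness_ed = 1.8)
  g2 <- build_ed_surfaces(p2)
  expect_equal(g2$cavity_volume, 8 * g1$cavity_volume, tolerance = 1e-9)
  expect_equal(g2$wall_volume, 8 * g1$wall_volume, tolerance = 1e-9)
  expect_equal(g2$endo_semi_axis_long, 2 * g1$endo_semi_axis_long,
               tolerance = 1e-9)
})

test_that("infeasible wall thickness is rejected", {
  bad <- patient_measurements(edv = 53, esv = 24.8, edp = 14.3,
                              lv_internal_diameter_ed = 2,
                              posterior_wall_thickness_ed = 1.5,
                              septal_wall_thickness_ed = 1.5)
  expect_error(build_ed_surfaces(bad), "thickness")
})

test_that("unloading rescale hits the target volume and conserves wall mass", {
  g <- build_ed_surfaces(ref_patient)
  # identity case
  g_same <- scale_to_unloaded(g, g$cavity_volume)
  expect_equal(g_same$endo_semi_axis_long, g$endo_semi_axis_long,
               tolerance = 1e-9)
  # chained with the unloading regression
  v0 <- klotz_unloaded_volume(53, 14.3)
  g0 <- scale_to_unloaded(g, v0)
  expect_equal(g0$cavity_volume, 27.25, tolerance = 0.001)
  expect_equal(g0$wall_volume, g$wall_volume, tolerance = 0.001)
  # wall volume verified against the independent slice oracle
  wall_num <- slice_volume(g0$epi_semi_axis_short, g0$epi_semi_axis_long,
                           g0$truncation_height) -
    slice_volume(g0$endo_semi_axis_short, g0$endo_semi_axis_long,
                 g0$truncation_height)
  expect_equal(wall_num, g$wall_volume, tolerance = 0.001)
  expect_error(scale_to_unloaded(g, g$cavity_volume * 1.1))
  expect_error(scale_to_unloaded(g, 0))
})

test_that("the structured hex mesh has the prescribed layout", {
  g0 <- ref_unloaded_geometry()
  m <- mesh_lv(g0, n_circ = 16, n_long = 10)
  expect_equal(nrow(m$conn), 8 * 16 * 10)
  expect_setequal(unique(m$layer), 1:8)
  tab <- table(m$region) / nrow(m$conn)
  expect_equal(unname(tab[["subendocardium"]]), 3 / 8)
  expect_equal(unname(tab[["midmyocardium"]]), 2 / 8)
  expect_equal(unname(tab[["subepicardium"]]), 3 / 8)
  expect_true(all(lvmech:::.hex_min_jac_cpp(m$nodes, m$conn) > 0))
  expect_error(mesh_lv(g0, n_circ = 4, n_long = 10))
  expect_error(mesh_lv(g0, n_circ = 16, n_long = 3))
})

test_that("mesh cavity volume converges to the analytic volume", {
  g0 <- ref_unloaded_geometry()
  va <- g0$cavity_volume
  e1 <- abs(mesh_cavity_volume(mesh_lv(g0, 8, 6), corrected = FALSE) - va)
  e2 <- abs(mesh_cavity_volume(mesh_lv(g0, 16, 12), corrected = FALSE) - va)
  expect_lt(e2, e1 / 2)
  # corrected volume is exact at the reference state by construction
  expect_equal(mesh_cavity_volume(mesh_lv(g0, 8, 6)), va, tolerance = 1e-10)
})
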