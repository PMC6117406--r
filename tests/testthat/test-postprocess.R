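test_that("ejection fraction arithmetic matches the clinical definition", {
  expect_equal(ejection_fraction(53, 24.8), 100 * (53 - 24.8) / 53)
  expect_equal(ejection_fraction(53, 24.8), 53.2, tolerance = 0.01)
  expect_equal(ejection_fraction(53, 31.4), 40.75, tolerance = 0.01)
  expect_equal(ejection_fraction(40, 40), 0)
  expect_warning(ef <- ejection_fraction(40, 45), "negative")
  expect_lt(ef, 0)
})

test_that("the torsion normalization evaluates its worked example", {
  expect_equal(torsion_formula(10, -5, 2, 3, 8), 4.69, tolerance = 0.005)
  # rigid rotation: equal ring rotations cancel
  expect_equal(torsion_formula(7, 7, 2, 3, 8), 0)
})

test_that("mesh torsion is zero under rigid rotation and scale-invariant", {
  mesh <- tiny_model()$mesh
  th <- 0.3
  Q <- rotation_xyz(c(0, 0, th))
  u_rot <- as.numeric(t(mesh$nodes %*% t(Q) - mesh$nodes))
  expect_lt(abs(torsion(mesh, u_rot)), 1e-9)

  # differential twist: apex ring rotated, base fixed
  nn <- nrow(mesh$nodes)
  z <- mesh$nodes[, 3]
  zb <- max(z); za <- min(z)
  ang <- 0.2 * (zb - z) / (zb - za)       # radians, largest at the apex
  x <- mesh$nodes
  u_tw <- as.numeric(t(cbind(x[, 1] * cos(ang) - x[, 2] * sin(ang) - x[, 1],
                             x[, 1] * sin(ang) + x[, 2] * cos(ang) - x[, 2],
                             0)))
  t1 <- torsion(mesh, u_tw)
  expect_gt(abs(t1), 0.1)
  # uniform scaling of the deformed configuration leaves torsion unchanged
  s <- 1.7
  u_sc <- s * (as.numeric(t(mesh$nodes)) + u_tw) - as.numeric(t(mesh$nodes))
  expect_equal(torsion(mesh, u_sc), t1, tolerance = 1e-9)
})

test_that("torsion sign convention: counterclockwise from apex is positive", {
  mesh <- tiny_model()$mesh
  # rotate the apex ring clockwise about +z, i.e. counterclockwise when the
  # observer looks from the apex (below, -z) toward the base
  z <- mesh$nodes[, 3]
  zb <- max(z); za <- min(z)
  ang <- -0.2 * (zb - z) / (zb - za)      # negative = clockwise about +z
  x <- mesh$nodes
  u_tw <- as.numeric(t(cbind(x[, 1] * cos(ang) - x[, 2] * sin(ang) - x[, 1],
                             x[, 1] * sin(ang) + x[, 2] * cos(ang) - x[, 2],
                             0)))
  expect_gt(torsion(mesh, u_tw), 0)
})

test_that("global strains vanish for identical states and match affine fields", {
  mod <- tiny_model()
  st0 <- new_state(mod)
  gs <- global_strains(mod, st0, st0)
  expect_equal(unname(gs), c(0, 0, 0), tolerance = 1e-12)

  # prescribed isochoric contraction: x,y shrink, z stretches
  lam <- 0.95
  A <- diag(c(lam, lam, 1 / lam^2))
  st1 <- st0
  st1$u <- as.numeric(t(tiny_model()$mesh$nodes %*% t(A) -
                        tiny_model()$mesh$nodes))
  gs <- global_strains(mod, st0, st1)
  # analytic Green strains of the affine map in the local bases
  E <- (t(A) %*% A - diag(3)) / 2
  bas <- mod$fibers$basis
  w <- element_fields(mod, st0$u)$vol
  exp_l <- 100 * sum(vapply(seq_len(nrow(bas$e_l)), function(e)
    drop(bas$e_l[e, ] %*% E %*% bas$e_l[e, ]), numeric(1)) * w) / sum(w)
  expect_equal(unname(gs["e_l"]), exp_l, tolerance = 1e-8)
})

test_that("sphericity is one for a hemisphere cavity and tracks the geometry", {
  geom <- structure(list(endo_semi_axis_long = 2, endo_semi_axis_short = 2,
                         epi_semi_axis_long = 2.5, epi_semi_axis_short = 2.5,
                         truncation_height = 0,
                         cavity_volume = trunc_ellipsoid_volume(2, 2, 0),
                         wall_volume = trunc_ellipsoid_volume(2.5, 2.5, 0) -
                           trunc_ellipsoid_volume(2, 2, 0)),
                    class = "lv_geometry")
  mesh <- mesh_lv(geom, 12, 8)
  u0 <- numeric(3 * nrow(mesh$nodes))
  # hemisphere: long axis (apex to base center) = radius, diameter = 2 radius
  expect_equal(sphericity_index(mesh, u0), 0.5, tolerance = 0.05)
  # reference LV geometry: ratio of construction axes
  mref <- tiny_model()$mesh
  g <- mref$geom
  expected <- (g$endo_semi_axis_long + g$truncation_height) /
    (2 * g$endo_semi_axis_short)
  expect_equal(sphericity_index(mref, numeric(3 * nrow(mref$nodes))),
               expected, tolerance = 0.1)
})

test_that("transmural profiles aggregate by layer with sane structure", {
  mod <- tiny_model()
  ed <- tiny_ed_state()
  prof <- transmural_profile(mod, ed$state, ed$state, time_es = -1)
  expect_equal(nrow(prof), 8)
  expect_equal(prof$depth, (1:8 - 0.5) / 8)
  # ES == ED gives zero ED-referenced strain; reference strain is tensile at ED
  expect_lt(max(abs(prof$eff_ed)), 1e-12)
  expect_true(all(prof$eff_ref > 0))
})
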