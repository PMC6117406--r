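test_that("the local triad is right-handed and orthonormal", {
  mod <- tiny_model()
  bas <- local_basis(mod$mesh)
  dots <- rowSums(bas$e_c * bas$e_l)
  expect_lt(max(abs(dots)), 1e-10)
  expect_lt(max(abs(rowSums(bas$e_l * bas$e_r))), 1e-10)
  expect_lt(max(abs(sqrt(rowSums(bas$e_c^2)) - 1)), 1e-10)
  # det[e_c e_l e_r] = +1
  d <- bas$e_c[, 1] * (bas$e_l[, 2] * bas$e_r[, 3] - bas$e_l[, 3] * bas$e_r[, 2]) -
       bas$e_c[, 2] * (bas$e_l[, 1] * bas$e_r[, 3] - bas$e_l[, 3] * bas$e_r[, 1]) +
       bas$e_c[, 3] * (bas$e_l[, 1] * bas$e_r[, 2] - bas$e_l[, 2] * bas$e_r[, 1])
  expect_lt(max(abs(d - 1)), 1e-10)
})

test_that("equatorial elements have circumferential e_c and radial e_r", {
  mesh <- tiny_model()$mesh
  bas <- local_basis(mesh)
  cen <- (mesh$nodes[mesh$conn[, 1], ] + mesh$nodes[mesh$conn[, 7], ]) / 2
  # element nearest the +x equator
  e <- which.min((cen[, 3])^2 + (atan2(cen[, 2], cen[, 1]))^2)
  expect_gt(abs(bas$e_c[e, 2]), 0.8)   # e_c ~ +/- y
  expect_gt(bas$e_r[e, 1], 0.8)        # e_r ~ +x (outward)
})

test_that("the basis rotates with a rigid rotation of the mesh", {
  mod <- tiny_model()
  mesh <- mod$mesh
  set.seed(42)
  th <- runif(3, 0, 2 * pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), sin(th[1]), 0, -sin(th[1]),
                 cos(th[1])), 3, 3)
  Rz <- matrix(c(cos(th[3]), sin(th[3]), 0, -sin(th[3]), cos(th[3]), 0,
                 0, 0, 1), 3, 3)
  Q <- Rz %*% Rx
  mesh2 <- mesh
  mesh2$nodes <- mesh$nodes %*% t(Q)
  b1 <- local_basis(mesh)
  b2 <- local_basis(mesh2)
  expect_lt(max(abs(b2$e_r - b1$e_r %*% t(Q))), 1e-9)
  expect_lt(max(abs(b2$e_c - b1$e_c %*% t(Q))), 1e-9)
})

test_that("the helix-angle rule hits its surface and midwall values", {
  expect_equal(helix_angle(0), 60)
  expect_equal(helix_angle(1), -60)
  expect_equal(helix_angle(0.5), 0)
  d <- (1:8 - 0.5) / 8
  expect_equal(helix_angle(d), 60 - 120 * d)
})

test_that("fiber and sheet fields are unit, orthogonal, and depth-driven", {
  mod <- tiny_model()
  fib <- mod$fibers
  expect_lt(max(abs(sqrt(rowSums(fib$f0^2)) - 1)), 1e-12)
  expect_lt(max(abs(sqrt(rowSums(fib$s0^2)) - 1)), 1e-12)
  expect_lt(max(abs(rowSums(fib$f0 * fib$s0))), 1e-12)
  expect_equal(fib$helix_angle, 60 - 120 * mod$mesh$depth)
  # angle depends only on transmural depth: a finer mesh agrees layer-wise
  mesh2 <- mesh_lv(ref_unloaded_geometry(), 16, 8)
  fib2 <- assign_fibers(mesh2)
  expect_equal(sort(unique(fib2$helix_angle)), sort(unique(fib$helix_angle)))
  # uniform layer spacing: mean helix angle ~ 0
  expect_lt(abs(mean(fib$helix_angle)), 1)
})
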