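mp_ref <- material_params()
ap_ref <- active_params()

test_that("invariants at the reference configuration and under fiber stretch", {
  fs <- list(f0 = c(1, 0, 0), s0 = c(0, 1, 0))
  inv <- compute_invariants(diag(3), fs$f0, fs$s0)
  expect_equal(inv$I1, 3)
  expect_equal(inv$I4f, 1)
  expect_equal(inv$I4s, 1)
  expect_equal(inv$I8fs, 0)
  expect_equal(inv$J, 1)
  expect_equal(inv$Eff, 0)
  # isochoric uniaxial stretch along the fiber
  lam <- 1.2
  F <- diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))
  inv <- compute_invariants(F, fs$f0, fs$s0)
  expect_equal(inv$I4f, 1.44)
  expect_equal(inv$Eff, 0.22)
  expect_equal(inv$J, 1)
  expect_error(compute_invariants(-diag(3), fs$f0, fs$s0), "inverted")
})

test_that("invariants match a dense-algebra oracle for random states", {
  set.seed(11)
  for (k in 1:20) {
    fs <- random_fs()
    F <- random_F()
    if (det(F) <= 0) next
    inv <- compute_invariants(F, fs$f0, fs$s0)
    C <- t(F) %*% F
    expect_equal(inv$I1, sum(diag(C)), tolerance = 1e-12)
    expect_equal(inv$I4f, drop(fs$f0 %*% C %*% fs$f0), tolerance = 1e-12)
    expect_equal(inv$I8fs, drop(fs$f0 %*% C %*% fs$s0), tolerance = 1e-12)
  }
})

test_that("the reference configuration is stress free", {
  fs <- list(f0 = c(1, 0, 0), s0 = c(0, 1, 0))
  S <- passive_pk2_stress(diag(3), fs$f0, fs$s0, mp_ref)
  expect_lt(max(abs(S)), 1e-12)
})

test_that("fiber term vanishes at I4f = 1 and in fiber compression", {
  f0 <- c(1, 0, 0); s0 <- c(0, 1, 0)
  # compression along the fiber: I4f < 1, so a_f must not contribute
  F <- diag(c(0.9, 1.02, 1.02))
  S1 <- passive_pk2_stress(F, f0, s0, mp_ref)
  mp_nofiber <- material_params(a_f = 0)
  S2 <- passive_pk2_stress(F, f0, s0, mp_nofiber)
  expect_equal(S1, S2, tolerance = 1e-14)
})

test_that("stress is the energy gradient (finite-difference check)", {
  set.seed(3)
  for (k in 1:30) {
    fs <- random_fs()
    F <- random_F(0.08)
    if (det(F) < 0.5) next
    S <- passive_pk2_stress(F, fs$f0, fs$s0, mp_ref)
    Sfd <- fd_stress_oracle(F, fs$f0, fs$s0, mp_ref)
    expect_lt(max(abs(Sfd - S)) / max(max(abs(S)), 1e-8), 1e-6)
  }
})

test_that("energy is rotation-invariant (objectivity)", {
  set.seed(5)
  for (k in 1:10) {
    fs <- random_fs()
    F <- random_F(0.1)
    if (det(F) <= 0.4) next
    th <- runif(3, 0, 2 * pi)
    Q <- rotation_xyz(th)
    e1 <- strain_energy(F, fs$f0, fs$s0, mp_ref)
    e2 <- strain_energy(Q %*% F, fs$f0, fs$s0, mp_ref)
    expect_equal(e1, e2, tolerance = 1e-10)
  }
})

test_that("uniaxial fiber stress is increasing in stretch (stable regime)", {
  f0 <- c(1, 0, 0); s0 <- c(0, 1, 0)
  lams <- seq(1.02, 1.3, length.out = 10)
  sig <- vapply(lams, function(l) {
    F <- diag(c(l, 1 / sqrt(l), 1 / sqrt(l)))
    S <- passive_pk2_stress(F, f0, s0, mp_ref)
    l^2 * S[1, 1]    # Cauchy fiber stress at J = 1
  }, numeric(1))
  expect_true(all(diff(sig) > 0))
})

test_that("active tension respects its limiting cases", {
  expect_equal(active_tension(0.1, 0, t_max = 0), 0)
  expect_equal(active_tension(0, 0, t_max = 0.1), 0)
  # l below the zero-tension sarcomere length produces no stress
  Eff_small <- ((ap_ref$l0 * 0.99 / ap_ref$lR)^2 - 1) / 2
  expect_equal(active_tension(0.15, Eff_small, t_max = 0.1), 0)
  # past full relaxation
  expect_equal(active_tension(5, 0, t_max = 0.1), 0)
  expect_error(active_tension(0.1, -0.51, t_max = 0.1))
})

test_that("peak activation at t0 matches the closed-form tension", {
  # Ct = 1 at t = t0; at Eff = 0 the sarcomere is at lR
  eca50 <- ap_ref$ca0_max / sqrt(exp(ap_ref$b_len * (ap_ref$lR - ap_ref$l0)) - 1)
  expected <- 0.1 * ap_ref$ca0^2 / (ap_ref$ca0^2 + eca50^2)
  expect_equal(active_tension(ap_ref$t0, 0, t_max = 0.1), expected,
               tolerance = 1e-12)
  # rising phase is below the peak
  expect_lt(active_tension(ap_ref$t0 / 2, 0, t_max = 0.1), expected)
})

test_that("total stress superposes passive and active parts", {
  f0 <- c(1, 0, 0); s0 <- c(0, 1, 0)
  F <- diag(c(1.1, 1 / sqrt(1.1), 1 / sqrt(1.1)))
  Sp <- passive_pk2_stress(F, f0, s0, mp_ref)
  # t = 0: no active contribution
  expect_equal(total_stress(F, f0, s0, mp_ref, t_max = 0.1, t = 0), Sp,
               tolerance = 1e-14)
  St <- total_stress(F, f0, s0, mp_ref, t_max = 0.1, t = ap_ref$t0)
  I4f <- 1.1^2
  T0 <- active_tension(ap_ref$t0, (I4f - 1) / 2, t_max = 0.1)
  expect_equal(St - Sp, T0 / I4f * (f0 %o% f0), tolerance = 1e-10)
  expect_equal(St, t(St))   # symmetry
})

test_that("zero-passive peak tension appears as a pure fiber dyad", {
  mp0 <- material_params(a = 1e-12, a_f = 0, a_s = 0, a_fs = 0)
  set.seed(8)
  fs <- random_fs()
  St <- total_stress(diag(3), fs$f0, fs$s0, mp0, t_max = 0.2, t = ap_ref$t0)
  eca50 <- ap_ref$ca0_max / sqrt(exp(ap_ref$b_len * (ap_ref$lR - ap_ref$l0)) - 1)
  T0 <- 0.2 * ap_ref$ca0^2 / (ap_ref$ca0^2 + eca50^2)
  expect_equal(St, T0 * (fs$f0 %o% fs$f0), tolerance = 1e-9)
})
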