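test_that("the scenario table encodes the six contractility patterns", {
  tab <- scenario_table(0.086, 0.117)
  expect_equal(tab$id, 1:6)
  expect_equal(tab$t_max_subendo, c(0.086, 0, 0, 0.043, 0.086, 0.086))
  expect_equal(tab$t_max_mid, c(0.086, 0.086, 0.086, 0.043, 0, 0.086))
  expect_equal(tab$t_max_subepi, c(0.086, 0.086, 0.117, 0.043, 0, 0))
  # scenario 1 uniform, scenario 4 uniformly halved
  expect_true(all(tab[1, 2:4] == 0.086))
  expect_true(all(tab[4, 2:4] == 0.043))
})

test_that("region-wise contractility maps onto the correct layers", {
  mod <- tiny_model()
  m2 <- set_tmax(mod, c(subendo = 0, mid = 0.05, subepi = 0.11))
  mesh <- mod$mesh
  expect_true(all(m2$tmax_el[mesh$layer <= 3] == 0))
  expect_true(all(m2$tmax_el[mesh$layer %in% 4:5] == 0.05))
  expect_true(all(m2$tmax_el[mesh$layer >= 6] == 0.11))
})

test_that("silencing the subendocardium reduces ejection fraction", {
  mod <- tiny_model()
  ed <- tiny_ed_state()
  b1 <- run_beat(set_tmax(mod, 0.1), ed$state, afterload_params(), dt = 0.02)
  b2 <- run_beat(set_tmax(mod, c(subendo = 0, mid = 0.1, subepi = 0.1)),
                 ed$state, afterload_params(), dt = 0.02)
  expect_gt(b1$ef, b2$ef)
  expect_gt(b2$esv, b1$esv)
})

test_that("scenario runs share every configuration field except contractility", {
  mod <- tiny_model()
  f1 <- lvmech:::config_fingerprint(list(mp = unclass(mod$mp),
                                         ap = unclass(mod$ap)))
  m2 <- set_tmax(mod, 0.2)
  f2 <- lvmech:::config_fingerprint(list(mp = unclass(m2$mp),
                                         ap = unclass(m2$ap)))
  expect_identical(f1, f2)
  expect_identical(scenario_table(0.08, 0.11), scenario_table(0.08, 0.11))
})
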