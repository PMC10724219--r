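test_that("Carreau viscosity matches its closed form and limits", {
  p <- rheology_params()
  expect_identical(carreau_viscosity(0, p), 0.056)
  expect_lt(abs(carreau_viscosity(1e9, p) - 0.0035), 1e-6)
  # direct evaluation at gamma = 1/lambda (independent hand check)
  expect_lt(abs(carreau_viscosity(1 / p$lambda_c, p) - 0.045510), 1e-6)
  expect_error(carreau_viscosity(-1, p), "gamma")
})

test_that("Carreau viscosity is monotone non-increasing and bounded", {
  p <- rheology_params()
  set.seed(11)
  g <- sort(runif(200, 0, 1e4))
  mu <- carreau_viscosity(g, p)
  expect_true(all(diff(mu) <= 0))
  expect_true(all(mu >= p$mu_inf & mu <= p$mu_zero))
})

test_that("rheology parameter invariants are enforced", {
  expect_error(rheology_params(mu_inf = 0.06), "mu_inf < mu_zero")
  expect_error(rheology_params(lambda_c = -1), "lambda_c")
  expect_error(rheology_params(n_index = 1.5), "n_index")
})

test_that("Poiseuille wall shear rate follows 4Q/(pi r^3)", {
  expect_identical(poiseuille_wall_shear_rate(0, 1e-3), 0)
  expect_equal(poiseuille_wall_shear_rate(1e-6, 1e-3), 1273.24,
               tolerance = 1e-5)
  g1 <- poiseuille_wall_shear_rate(3e-6, 1e-3)
  expect_equal(poiseuille_wall_shear_rate(3e-6, 2e-3), g1 / 8)
  expect_error(poiseuille_wall_shear_rate(1e-6, 0), "radius")
})

test_that("Poiseuille resistance scales as 8 mu L / (pi r^4)", {
  cd <- conduit("seg", length = 0.01, radius = 0.002)
  expect_equal(poiseuille_resistance(0.0035, cd), 5.5705e6,
               tolerance = 1e-4)
  expect_equal(poiseuille_resistance(0.0035, conduit("x", 0.02, 0.002)),
               2 * poiseuille_resistance(0.0035, cd))
  expect_equal(poiseuille_resistance(0.0035, conduit("x", 0.01, 0.001)),
               16 * poiseuille_resistance(0.0035, cd))
  # round trip back to the viscosity
  R <- poiseuille_resistance(0.0042, cd)
  expect_equal(R * pi * cd$radius^4 / (8 * cd$length), 0.0042)
})

test_that("pressure drop is bilinear in resistance and flow", {
  expect_equal(pressure_drop(1e8, 1e-6), 100)
  # product of the printed healthy ACA resistance and flow
  expect_equal(pressure_drop(3.34e8, 9.64e-7), 322.0, tolerance = 1e-3)
  expect_identical(pressure_drop(1e8, 0), 0)
  expect_equal(pressure_drop(3 * 1e8, 2 * 1e-6), 6 * pressure_drop(1e8, 1e-6))
  expect_equal(pressure_drop(1e8, -1e-6), -100)
})

test_that("effective segment resistance closes the Carreau-Poiseuille loop", {
  p <- rheology_params()
  cd <- conduit("seg", length = 0.01, radius = 1.57e-3)
  # zero flow -> zero-shear viscosity
  expect_equal(effective_segment_resistance(0, cd, p),
               poiseuille_resistance(p$mu_zero, cd))
  # very large flow -> infinite-shear viscosity within 0.1%
  expect_equal(effective_segment_resistance(1e-2, cd, p),
               poiseuille_resistance(p$mu_inf, cd), tolerance = 1e-3)
  # equals the explicit composition to machine precision (the shear rate
  # is flow-determined, so the fixed point closes in one step)
  for (Q in c(3.2e-6, 1e-7, 5e-5)) {
    gam <- poiseuille_wall_shear_rate(Q, cd$radius)
    expect_identical(effective_segment_resistance(Q, cd, p),
                     poiseuille_resistance(carreau_viscosity(gam, p), cd))
  }
})
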