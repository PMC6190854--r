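test_that("bending strain is the height-to-curvature ratio", {
  expect_equal(bending_strain(0.1, 10), 0.01, tolerance = 1e-15)
  expect_identical(bending_strain(0, 5), 0)
  expect_lt(abs(bending_strain(1, 1e12)), 1e-11)   # flat-sheet limit
  expect_error(bending_strain(1, 0), "nonzero")
})

test_that("second moment of area: rectangle closed form, cubic scaling, parallel axis", {
  unit_w <- function(y) rep(1, length(y))
  I1 <- moment_of_inertia(unit_w, -0.5, 0.5)
  expect_equal(I1, 1 / 12, tolerance = 1e-6)

  I2 <- moment_of_inertia(unit_w, -1, 1)   # height 2
  expect_equal(I2 / I1, 8, tolerance = 1e-6)

  # sampled profile input and a non-centroidal axis
  prof <- data.frame(y = seq(-0.5, 0.5, length.out = 11), width = 1)
  expect_equal(moment_of_inertia(prof), 1 / 12, tolerance = 1e-6)
  I_shift <- moment_of_inertia(unit_w, -0.5, 0.5, axis = 0.3)
  expect_gt(I_shift, I1)
  expect_equal(I_shift, 1 / 12 + 0.3^2, tolerance = 1e-6)  # parallel-axis theorem

  expect_error(moment_of_inertia(function(y) rep(0, length(y)), 0, 1), "area")
})

test_that("bending moment E*I/R agrees with the direct stress integral", {
  expect_identical(bending_moment(1, 1, 1), 1)
  expect_equal(bending_moment(2, 1 / 12, 4), 1 / 24, tolerance = 1e-12)
  # integral form on a rectangular section: tau = (E/R) * integral y^2 dA
  E <- 2; R <- 4
  I_quad <- moment_of_inertia(function(y) rep(1, length(y)), -0.5, 0.5)
  expect_equal(bending_moment(E, I_quad, R), E / R * I_quad, tolerance = 1e-12)
  expect_equal(bending_moment(E, I_quad, R), 1 / 24, tolerance = 1e-6)
  # moment-arm form: tau = F * y_p at matching load and arm
  F <- 3; y_p <- 0.25
  expect_equal(F * y_p, bending_moment(E = F * y_p / I_quad, I = I_quad, R = 1),
               tolerance = 1e-12)
  expect_error(bending_moment(1, 1, 0), "nonzero")
})

test_that("Euler critical force: closed form, scaling, input validation", {
  expect_equal(euler_critical_force(1, 1, pi), 1, tolerance = 1e-15)
  expect_equal(euler_critical_force(2, 3, 2), 3 * pi^2 / 2, tolerance = 1e-12)
  expect_equal(euler_critical_force(1, 1, 0.5) / euler_critical_force(1, 1, 1), 4,
               tolerance = 1e-12)
  expect_error(euler_critical_force(0, 1, 1), "positive")
  expect_error(euler_critical_force(1, 1, -2), "positive")
})

test_that("mode shape: pinned ends, midspan maximum, beam-equation residual", {
  expect_equal(mode_shape(2, 3, c(0, 3)), c(0, 0), tolerance = 1e-14)
  expect_equal(mode_shape(2, 3, 1.5), 2, tolerance = 1e-12)
  expect_error(mode_shape(1, 1, 1.5), "x_p")
  expect_lt(mode_ode_residual(1, 1, 1000), 1e-4)
  expect_lt(mode_ode_residual(0.3, 2.5, 1000), 1e-4)
})

test_that("discrete chain critical load converges to the Euler force at O(1/n^2)", {
  Fc <- euler_critical_force(1, 1, 1)
  F50 <- discrete_chain_critical_load(50, 1, 1, 1)
  expect_lt(abs(F50 - Fc) / Fc, 0.02)

  ns <- c(8, 16, 32, 64, 128)
  errs <- vapply(ns, function(n) abs(discrete_chain_critical_load(n, 1, 1, 1) - Fc) / Fc, 0)
  expect_true(all(diff(errs) < 0))
  # empirical order ~ 2: quadrupling accuracy per doubling
  rates <- errs[-length(errs)] / errs[-1]
  expect_true(all(rates > 3 & rates < 5))

  # linearity in E*I (to eigen-solver precision)
  expect_equal(discrete_chain_critical_load(32, 3, 2, 1),
               6 * discrete_chain_critical_load(32, 1, 1, 1), tolerance = 1e-9)
  expect_error(discrete_chain_critical_load(2, 1, 1, 1), ">= 3")
})

test_that("detected critical load is amplitude-independent for small bending", {
  Lc <- 1
  amps <- 10^seq(-6, -2, by = 1) * Lc
  loads <- vapply(amps, function(a) critical_load_from_amplitude(a, Lc, 1, 1), 0)
  spread <- (max(loads) - min(loads)) / min(loads)
  expect_lt(spread, 0.005)
  expect_lt(abs(loads[1] - euler_critical_force(1, 1, Lc)) / loads[1], 1e-3)
})
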