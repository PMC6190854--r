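test_that("x balance residual vanishes in the equal-force, orthogonal and collinear cases", {
  eq120 <- force_state(F_C_xz = 1, F_R_xz = 1, F_L_xz = 1,
                       theta1 = pi / 3, theta2 = pi / 3)
  expect_equal(x_balance_residual(eq120), 0, tolerance = 1e-15)

  ortho <- force_state(F_C_xz = 0, F_R_xz = 1, F_L_xz = 1,
                       theta1 = pi / 2, theta2 = pi / 2)
  expect_equal(x_balance_residual(ortho), 0, tolerance = 1e-15)

  collinear <- force_state(F_C_xz = 2, F_R_xz = 1, F_L_xz = 1,
                           theta1 = 0, theta2 = 0)
  expect_equal(x_balance_residual(collinear), 0, tolerance = 1e-15)
})

test_that("vertical balance uses each force's own angle", {
  fr <- 1; fl <- 2; fc <- 0.5
  a1 <- 0.3; a2 <- 0.8; a3 <- 1.1
  fext <- fr * cos(a1) + fl * cos(a2) + fc * cos(a3)
  expect_equal(y_balance_residual(fext, fr, fl, fc, a1, a2, a3), 0, tolerance = 1e-15)
  # using a single shared angle would not balance
  expect_gt(abs(y_balance_residual(fext, fr, fl, fc, a1, a1, a1)), 1e-3)
})

test_that("symmetric angle inversion: 120-degree condition, closing, limits, no-solution", {
  th <- solve_symmetric_angles(F_C = 1, F_side = 1)
  expect_equal(unname(th[1] + th[2]), 2 * pi / 3, tolerance = 1e-15)

  th45 <- solve_symmetric_angles(sqrt(2), 1)
  expect_equal(unname(th45[1]), pi / 4, tolerance = 1e-12)

  th90 <- solve_symmetric_angles(0, 1)
  expect_equal(unname(th90[1]), pi / 2, tolerance = 1e-15)

  expect_error(solve_symmetric_angles(2.01, 1), "no symmetric solution")
  expect_error(solve_symmetric_angles(1, 0), "F_side")

  # round trip through the balance residual
  for (fc in seq(0, 2, length.out = 21)) {
    th <- solve_symmetric_angles(fc, 1)
    st <- force_state(fc, 1, 1, th[1], th[2])
    expect_lt(abs(x_balance_residual(st)), 1e-12)
  }

  # monotone non-increasing opening angle as the pull grows
  fgrid <- seq(0, 2, length.out = 100)
  sums <- vapply(fgrid, function(fc) sum(solve_symmetric_angles(fc, 1)), 0)
  expect_true(all(diff(sums) <= 0))
})

test_that("chain straightening angle reaches pi at force equality", {
  expect_equal(straightening_angle(1, 1), pi, tolerance = 1e-15)
  expect_equal(straightening_angle(0, 1), pi / 2, tolerance = 1e-15)
  expect_equal(straightening_angle(0.5, 1), 2 * pi / 3, tolerance = 1e-12)
  expect_error(straightening_angle(1.1, 1), "no solution")
  expect_error(straightening_angle(1, 0), "F_R2")
})

test_that("relaxation leaves an unloaded resting ring untouched and respects Hooke's law", {
  fx <- make_fixture("ring", list(n = 12))
  eq <- relax_ring(fx$cells, fx$junctions, tol = 1e-10)
  expect_lt(max_position_diff(eq$cells, fx$cells), 1e-9)

  # single spring: unit stiffness, unit force -> unit extension
  ch <- make_fixture("chain", list(n = 2, spacing = 1, stiffness = 1))
  eq1 <- relax_ring(ch$cells, ch$junctions,
                    applied = data.frame(cell_id = 2, fx = 1, fy = 0),
                    pinned = 1, tol = 1e-10)
  expect_equal(eq1$cells$x[2], 2, tolerance = 1e-8)
})

test_that("internal junction forces over a closed unloaded ring sum to zero", {
  fx <- make_fixture("ring", list(n = 16, jitter = 0.05), seed = 42)
  eq <- relax_ring(fx$cells, fx$junctions, tol = 1e-10)
  # at the fixed point every net force is < tol, so their sum (pure internal
  # spring forces, Newton pairs) must vanish
  expect_lt(max(abs(colSums(eq$forces))), 1e-9)
  expect_lt(max(sqrt(rowSums(eq$forces^2))), 1e-10)
})

test_that("a radial pull produces a droplet whose opening angle closes monotonically", {
  fx <- make_fixture("ring", list(n = 24))
  pulls <- seq(0.5, 4, length.out = 8)
  sums <- numeric(length(pulls))
  aspects <- numeric(length(pulls))
  asyms <- numeric(length(pulls))
  for (i in seq_along(pulls)) {
    eq <- relax_ring(fx$cells, fx$junctions,
                     applied = data.frame(cell_id = 1, fx = pulls[i], fy = 0),
                     pinned = 13, anchor_stiffness = 0.02, tol = 1e-8)
    sums[i] <- opening_angle_sum(eq)
    m <- shape_metrics(contour_xy(eq$cells$x, eq$cells$y))
    aspects[i] <- m$aspect_ratio
    asyms[i] <- m$asymmetry
  }
  expect_true(all(aspects > 1))
  expect_true(all(asyms > 0.01))          # one-sided pull: teardrop, not oval
  expect_true(all(diff(sums) < 0))        # theta1 + theta2 closes with the pull
  expect_true(all(diff(aspects) > 0))
})

test_that("relaxed equilibria match direct energy minimization", {
  for (n in c(12, 20, 30)) {
    fx <- make_fixture("ring", list(n = n))
    applied <- data.frame(cell_id = 1, fx = 1.5, fy = 0.3)
    pin <- n %/% 2 + 1
    eq <- relax_ring(fx$cells, fx$junctions, applied = applied, pinned = pin,
                     anchor_stiffness = 0.5, tol = 1e-9)
    orc <- oracle_equilibrium(fx$cells, fx$junctions, applied = applied,
                              pinned = pin, anchor_stiffness = 0.5)
    expect_lt(max_position_diff(eq$cells, orc), 1e-6)
  }
})

test_that("straightening is visible at the rim: theta3 approaches pi under load", {
  fx <- make_fixture("ring", list(n = 24))
  eq <- relax_ring(fx$cells, fx$junctions,
                   applied = data.frame(cell_id = 1, fx = 6, fy = 0),
                   pinned = 13, anchor_stiffness = 0.02, tol = 1e-8)
  fs <- eq$force_state
  expect_gt(fs$theta3, 0.97 * pi)
  expect_lt(abs(fs$F_R1_xz - fs$F_R2_xz) / fs$F_R2_xz, 0.2)
})

test_that("non-convergence raises a typed error and invalid inputs are caught", {
  fx <- make_fixture("ring", list(n = 8))
  expect_error(
    relax_ring(fx$cells, fx$junctions,
               applied = data.frame(cell_id = 1, fx = 1, fy = 0),
               pinned = 5, max_iter = 2, tol = 1e-12),
    class = "cryptmech_convergence_error")
  bad <- fx$junctions
  bad$stiffness[1] <- -1
  expect_error(relax_ring(fx$cells, bad), "stiffness")
  # disconnected graph
  two <- make_fixture("chain", list(n = 4))
  two$junctions <- two$junctions[-2, ]
  expect_error(relax_ring(two$cells, two$junctions), "connected")
})
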