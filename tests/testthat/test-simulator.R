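quick_cfg <- function(...) sim_config(ring_size = 16, relax_tol = 1e-6, ...)

test_that("a null run stays a round opening with no displacement or profile", {
  fit <- run_crypt_sim(quick_cfg(n_divisions = 0))
  tr <- fit$trajectory
  expect_identical(nrow(tr), 1L)
  expect_identical(tr$label, "round")
  # a regular 16-gon: 4*pi*A/P^2 = (pi/16)/tan(pi/16)
  expect_equal(tr$iso_ratio, (pi / 16) / tan(pi / 16), tolerance = 1e-9)
  expect_identical(attr(fit$ledger, "S_x"), 0)
  expect_null(fit$depth)
})

test_that("lossless divisions leave no net displacement", {
  fit <- run_crypt_sim(quick_cfg(n_divisions = 5, F_v = 0, K_spring = 1))
  expect_identical(attr(fit$ledger, "S_x"), 0)
  expect_true(all(fit$trajectory$S_x == 0))
})

test_that("trajectory displacement equals the ledger recomputed from the event log", {
  fit <- run_crypt_sim(quick_cfg(n_divisions = 15))
  led <- fit$ledger
  recomputed <- accumulate_displacement(data.frame(F = led$F, K_spring = led$K_spring,
                                                   F_v = led$F_v))
  expect_identical(attr(led, "S_x"), attr(recomputed, "S_x"))
  expect_identical(fit$trajectory$S_x[-1], recomputed$S_x_cumulative)
})

test_that("EMT feedback fires above the Euler load and caps the pull", {
  cfg <- quick_cfg(n_divisions = 10)
  st <- new_sim_state(cfg)
  st$step <- 1L

  st$F_C_xz <- 0.5 * cfg$F_crit
  out <- emt_feedback(st, cfg)
  expect_identical(out$n_emt_last_step, 0L)
  expect_identical(out$F_C_xz, st$F_C_xz)

  st$F_C_xz <- 1.5 * cfg$F_crit
  st$y_p <- 0.1
  out <- emt_feedback(st, cfg)
  expect_gte(out$n_emt_last_step, 1L)
  expect_lte(out$F_C_xz, cfg$F_crit * (1 + cfg$emt_tolerance_band))
  expect_lt(out$y_p, 0.1)
  ev <- out$emt_events[[1]]
  expect_gte(ev$force_at_trigger, cfg$F_crit)

  # disabled feedback passes the state through
  cfg_off <- quick_cfg(n_divisions = 10, emt_enabled = FALSE)
  out_off <- emt_feedback(st, cfg_off)
  expect_identical(out_off$F_C_xz, st$F_C_xz)
})

test_that("opening classification follows the documented threshold table", {
  circ <- shape_metrics(make_fixture("ellipse", list(a = 1, b = 1, n = 360)))
  expect_identical(classify_opening(circ), "round")

  td <- make_fixture("teardrop", list(n = 400))
  pts <- td$points
  pts[, 1] <- pts[, 1] * 1.8 / shape_metrics(td)$aspect_ratio  # stretch to aspect 1.8
  mtd <- shape_metrics(contour_xy(pts))
  expect_equal(mtd$aspect_ratio, 1.8, tolerance = 0.05)
  expect_gt(mtd$asymmetry, 0.1)
  expect_identical(classify_opening(mtd), "droplet")

  long <- shape_metrics(make_fixture("ellipse", list(a = 9, b = 1, n = 360)))
  expect_identical(classify_opening(long), "linear")

  mid <- shape_metrics(make_fixture("ellipse", list(a = 1.3, b = 1, n = 360)))
  expect_identical(classify_opening(mid), "oval")
})

test_that("groove labels arise from composing neighbouring linear openings", {
  expect_identical(compose_groove(c("linear", "linear")), "groove")
  expect_identical(compose_groove(c("linear", "linear", "linear")), "groove")
  expect_identical(compose_groove(c("round", "linear")), "linear")
  expect_identical(compose_groove("linear"), "linear")
  expect_error(compose_groove(c("linear", "blob")), "unknown")
})

test_that("depth attenuation reproduces the exponential law and stays strictly decreasing", {
  cfg <- quick_cfg(n_cross_sections = 5, attenuation_lambda = 0.5)
  prof <- depth_profile(1, cfg)
  expect_equal(prof$S_x_m, exp(-0.5 * (0:4)), tolerance = 1e-12)
  expect_true(all(diff(prof$S_x_m) < 0))
  expect_true(all(diff(prof$D_L) > 0))

  # lambda -> infinity: only the surface section is displaced
  steep <- depth_profile(1, quick_cfg(attenuation_lambda = 50))
  expect_lt(max(steep$S_x_m[-1]), 1e-10)
  expect_equal(steep$S_x_m[1], 1, tolerance = 1e-12)

  # additive cell lengths shift sections but may not break monotonicity
  ok <- quick_cfg(A_L_schedule = c(0.4, 0.2, 0.1, 0.05, 0))
  expect_true(all(diff(depth_profile(1, ok)$S_x_m) < 0))
  bad <- quick_cfg(A_L_schedule = c(0, 10, 0, 0, 0))
  expect_error(depth_profile(1, bad), "config error")

  expect_error(depth_profile(0, cfg), "positive")
  expect_error(sim_config(attenuation_lambda = -1), "attenuation_lambda")
})

test_that("a short run walks forward through the shape classes and is reproducible", {
  cfg <- quick_cfg(n_divisions = 40, emt_enabled = FALSE)
  fit <- run_crypt_sim(cfg)
  tr <- fit$trajectory
  ord <- match(tr$label, opening_class_order())
  expect_false(is.unsorted(ord))
  expect_true(all(diff(tr$F_C_xz) > 0))
  expect_true(all(diff(tr$S_x) >= 0))
  expect_gt(tr$aspect_ratio[nrow(tr)], 1)
  expect_true(all(diff(fit$depth$S_x_m) < 0))

  fit2 <- run_crypt_sim(cfg)
  expect_identical(fit$trajectory, fit2$trajectory)

  # bit-identical serialized outputs
  d1 <- tempfile(); d2 <- tempfile()
  write_outputs(fit, d1); write_outputs(fit2, d2)
  for (f in c("trajectory.csv", "ledger.csv", "depth.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("model-object methods expose the fit the usual way", {
  fit <- run_crypt_sim(quick_cfg(n_divisions = 8))
  expect_s3_class(fit, "crypt_sim")
  expect_output(print(fit), "Crypt-opening")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.crypt_sim")
  expect_output(print(sm), "Euler load")
  cf <- coef(fit)
  expect_equal(unname(cf["F_crit"]), fit$F_crit, tolerance = 1e-15)
  expect_true(all(residuals(fit) < fit$config$relax_tol))
  refit <- simulate(fit)
  expect_identical(refit$trajectory, fit$trajectory)
  pdf(NULL)
  expect_no_error(plot(fit))
  dev.off()
})
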