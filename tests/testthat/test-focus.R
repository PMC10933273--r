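test_that("bead images are deterministic, blur with defocus and conserve light", {
  a <- render_bead_image(150, noise_level = 0.05, seed = 9)
  b <- render_bead_image(150, noise_level = 0.05, seed = 9)
  expect_identical(a$pixels, b$pixels)
  # blur is monotone in |defocus|: the in-focus image is the sharpest
  i0 <- render_bead_image(0, noise_level = 0)
  i300 <- render_bead_image(300, noise_level = 0)
  expect_gt(max(i0$pixels), max(i300$pixels))
  expect_false(identical(i0$pixels, i300$pixels))
  # numerical-integral oracle: total intensity conserved within 1%
  totals <- vapply(c(0, 100, 300, 500), function(z)
    sum(render_bead_image(z, noise_level = 0)$pixels), numeric(1))
  expect_true(all(abs(totals / totals[1] - 1) < 0.01))
  expect_true(all(i300$pixels >= 0))
})

test_that("match score is 1000 for self, symmetric, and near zero for noise", {
  tpl <- render_bead_image(300, noise_level = 0)
  expect_identical(match_score(tpl, tpl), 1000)
  live <- render_bead_image(250, noise_level = 0.02, seed = 2)
  expect_equal(match_score(tpl, live), match_score(live, tpl))
  expect_true(abs(match_score(tpl, live)) <= 1000)
  # independent noise fields share no structure
  set.seed(7)
  n1 <- matrix(rnorm(1600), 40, 40)
  n2 <- matrix(rnorm(1600), 40, 40)
  expect_lt(abs(match_score(n1, n2)), 100)
  expect_error(match_score(matrix(1, 40, 40), tpl), class = "trapkin_score_error")
  expect_error(match_score(matrix(0, 20, 20), tpl), class = "trapkin_config_error")
})

test_that("score versus defocus peaks at the template defocus, locally quadratic", {
  crv <- focus_score_curve(seq(200, 400, by = 5))
  expect_equal(crv$defocus[which.max(crv$score)], 300)
  near <- crv[abs(crv$defocus - 300) <= 50, ]
  fit <- lm(score ~ poly(defocus, 2, raw = TRUE), near)
  cf <- coef(fit)
  expect_lt(cf[3], 0)                       # concave peak
  expect_equal(unname(-cf[2] / (2 * cf[3])), 300, tolerance = 0.02)  # vertex
  # flanks are monotone towards the vertex
  flank <- focus_score_curve(seq(0, 250, by = 25))
  expect_true(all(diff(flank$score) > 0))
})

test_that("slope calibration matches the derivative oracle and fails at the vertex", {
  score_fn <- make_score_function(noise_level = 0)
  st <- focus_state(z_stage = 80)
  st <- calibrate_slope(st, score_fn, excursion = 100)
  # analytic differentiation oracle: central difference at the excursion
  # midpoint on the noiseless curve
  h <- 0.5
  mid <- 80 + 50
  oracle <- (score_fn(mid + h) - score_fn(mid - h)) / (2 * h)
  expect_equal(st$slope, oracle, tolerance = 0.05)
  # at the vertex the curve is flat: calibration must fail
  expect_error(calibrate_slope(focus_state(z_stage = 300), score_fn,
                               excursion = 2),
               class = "trapkin_calibration_error")
  # slope sign flips on opposite sides of the vertex
  lo <- calibrate_slope(focus_state(z_stage = 100), score_fn)$slope
  hi <- calibrate_slope(focus_state(z_stage = 450), score_fn)$slope
  expect_true(sign(lo) != sign(hi))
})

test_that("the proportional controller restores a step and bounds ramp drift", {
  score_fn <- make_score_function(noise_level = 0)
  st <- calibrate_slope(focus_state(z_stage = 80), score_fn)
  expect_equal(drift_correction_step(st, st$score_setpoint), 0)
  expect_error(drift_correction_step(focus_state(), 500),
               class = "trapkin_calibration_error")
  # 30 nm step drift: the linearised loop recovers within one cycle
  drift_step <- inject_drift(3, drift_rate = 0, seed = 1)
  drift_step$drift <- ifelse(drift_step$time >= 1, 30, 0)
  log1 <- run_focus_lock(st, drift_step, score_fn, z_operating = 80)
  expect_lt(abs(log1$z_error[nrow(log1)]), 2)
  # 5 nm/s ramp: sampled-control bound |error| <= rate x interval (+ margin)
  ramp <- inject_drift(12, drift_rate = 5, seed = 1)
  log2 <- run_focus_lock(st, ramp, score_fn, z_operating = 80)
  late <- log2[log2$time > 3, ]
  expect_lt(max(abs(late$z_error)), 5 * st$correction_interval + 2)
})

test_that("closing the loop reduces score variance under drift", {
  tpl <- render_bead_image(300, noise_level = 0)
  drift <- inject_drift(20, drift_rate = 3, diffusion = 5, seed = 14)
  score_on <- make_score_function(tpl, noise_level = 0.01, seed = 3)
  st <- calibrate_slope(focus_state(z_stage = 80), make_score_function(tpl, 0))
  log_on <- run_focus_lock(st, drift, score_on, z_operating = 80)
  score_off <- make_score_function(tpl, noise_level = 0.01, seed = 3)
  log_off <- run_focus_lock(st, drift, score_off, z_operating = 80,
                            controller_on = FALSE)
  expect_lt(var(log_on$score), var(log_off$score))
  expect_lt(var(log_on$z_error), var(log_off$z_error))
})

test_that("surface finding brackets the contact and is exact without noise", {
  # noiseless: reported contact within (z*, z* + step], refined to z*
  app <- simulate_surface_approach(73, noise_sd = 0, seed = 1)
  res <- find_surface(app, step = 10, z_start = 0, z_max = 200)
  expect_gte(res$z_trigger, 73)
  expect_lte(res$z_trigger, 83)
  expect_equal(res$z_contact, 73, tolerance = 1e-6)
  # pre-contact the trapped-bead score is flat
  pre <- res$scores[res$z < 73]
  expect_lt(diff(range(pre)), 1e-9)
  # starting already in contact: declared at the first step
  app2 <- simulate_surface_approach(-50, noise_sd = 0, seed = 1)
  res2 <- find_surface(app2, step = 10, z_start = 0, z_max = 200)
  expect_equal(res2$z_trigger, 10)
  expect_lte(res2$z_contact, 10)
  # no contact in range: explicit failure
  app3 <- simulate_surface_approach(500, noise_sd = 0, seed = 1)
  expect_error(find_surface(app3, z_max = 200), class = "trapkin_surface_error")
})
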