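motor_off <- function(...) motor_model(on_rate_model = on_rate_constant(0), ...)

test_that("zero temperature with no motor gives a noiseless bead at the trap centre", {
  x <- simulate_trace(trap_config(temperature = 0), dither_config(),
                      motor_off(), d_B_MT = 20, duration = 1, seed = 3)
  expect_lt(var(x$bead_position), 1e-12)
  expect_true(all(abs(x$force) < 1e-9))
  expect_identical(nrow(x$true_events), 0L)
})

test_that("identical configuration and seed reproduce the trace exactly", {
  a <- simulate_trace(duration = 2, seed = 99)
  b <- simulate_trace(duration = 2, seed = 99)
  expect_identical(a$force, b$force)
  expect_identical(a$true_events, b$true_events)
  c <- simulate_trace(duration = 2, seed = 100)
  expect_false(identical(a$force, c$force))
})

test_that("dithered motor-free bead tracks the trap below the force threshold", {
  x <- simulate_trace(trap_config(), dither_config(TRUE, 20, 200),
                      motor_off(), d_B_MT = 20, duration = 10, seed = 5)
  # drag-force oracle: gamma * v for a triangle at 2 * p2p * f nm/s
  gamma <- drag_coefficient(560)
  v <- 2 * 200 * 20
  expect_lt(gamma * v, 0.1)  # lag force far below the 1 pN threshold
  # the bead rides the trap: zero mean lag, fluctuations purely thermal
  expect_lt(abs(mean(x$bead_position - x$trap_position)), 1)
  kT_over_k <- thermal_energy(298) / 0.045
  expect_equal(var(x$bead_position - x$trap_position), kT_over_k,
               tolerance = 0.15)
  ev <- detect_events_dithered(x)
  expect_identical(nrow(ev), 0L)
})

test_that("every bound sample lies inside exactly one true event", {
  x <- simulate_trace(trap_config(),
                      dither_config(),
                      motor_model(on_rate_model = on_rate_constant(3),
                                  off_rate_unloaded = 3),
                      d_B_MT = 20, duration = 20, seed = 8)
  ev <- x$true_events
  expect_gt(nrow(ev), 3)
  expect_true(all(ev$unbind_time > ev$bind_time))
  # events are time-ordered and non-overlapping
  if (nrow(ev) > 1) expect_true(all(ev$bind_time[-1] >= ev$unbind_time[-nrow(ev)]))
  # event times accumulate over substeps: allow float-level tolerance
  inside <- rowSums(outer(x$time, ev$bind_time - 1e-9, ">=") &
                    outer(x$time, ev$unbind_time - 1e-9, "<"))
  expect_true(all(inside[x$motor_bound] == 1))
  expect_true(all(inside[!x$motor_bound] == 0))
})

test_that("geometry gate suppresses binding beyond tether reach", {
  x <- simulate_trace(trap_config(), dither_config(),
                      motor_model("K560", on_rate_model = on_rate_constant(5)),
                      d_B_MT = 80, duration = 10, seed = 2)
  expect_identical(nrow(x$true_events), 0L)
})

test_that("invalid simulation inputs fail loudly", {
  expect_error(simulate_trace(duration = 0), class = "trapkin_config_error")
  expect_error(simulate_trace(duration = 1, d_B_MT = -5),
               class = "trapkin_config_error")
  expect_error(simulate_trace(duration = 1, internal_dt = 1e-3),
               class = "trapkin_stability_error")
  expect_error(trap_config(sample_rate = -1), class = "trapkin_config_error")
})

test_that("sweeps tag every cell and reproduce under the master seed", {
  d <- corrected_distance(seq(0, 80, by = 20), 0.12)
  sw <- generate_sweep(d_values = d, duration = 0.5, seed = 17)
  expect_length(sw$traces, 5)
  expect_equal(sort(unique(sw$cells$d_B_MT)), sort(d))
  expect_equal(vapply(sw$traces, function(t) t$config$d_B_MT, numeric(1)),
               sw$cells$d_B_MT)
  sw2 <- generate_sweep(d_values = d, duration = 0.5, seed = 17)
  expect_identical(lapply(sw$traces, `[[`, "force"),
                   lapply(sw2$traces, `[[`, "force"))
  # zero repeats: an empty collection, not an error
  sw0 <- generate_sweep(d_values = d, reps = 0, duration = 0.5, seed = 17)
  expect_length(sw0$traces, 0)
  expect_error(generate_sweep(d_values = numeric(0)),
               class = "trapkin_config_error")
})

test_that("drift injection reproduces its stated displacement", {
  d0 <- inject_drift(10, drift_rate = 0, diffusion = 0, seed = 1)
  expect_true(all(d0$drift == 0))
  d1 <- inject_drift(10, drift_rate = 5, diffusion = 0, seed = 1)
  expect_equal(d1$drift[nrow(d1)], 50)
  d2 <- inject_drift(10, drift_rate = 0, diffusion = 3, seed = 4)
  d3 <- inject_drift(10, drift_rate = 0, diffusion = 3, seed = 4)
  expect_identical(d2$z, d3$z)
  expect_gt(var(d2$z), 0)
  expect_error(inject_drift(10, drift_rate = Inf), class = "trapkin_config_error")
})

test_that("traces round-trip through the delimited text format", {
  x <- simulate_trace(trap_config(),
                      dither_config(TRUE, 20, 200),
                      motor_model(on_rate_model = on_rate_constant(2),
                                  off_rate_unloaded = 2),
                      d_B_MT = 15, duration = 2, seed = 21)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trace(x, path)
  y <- read_trace(path)
  expect_equal(y$force, x$force, tolerance = 1e-6)
  expect_equal(y$config$trap$stiffness, 0.045)
  expect_equal(y$config$d_B_MT, 15)
  expect_true(y$config$dither$enabled)
  expect_equal(y$true_events$bind_time, x$true_events$bind_time, tolerance = 1e-9)
  # bare two-column instrument tables are accepted
  bare <- withr::local_tempfile(fileext = ".txt")
  utils::write.table(data.frame(t = x$time[1:100], f = x$force[1:100]), bare,
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  z <- read_trace(bare)
  expect_equal(z$force, x$force[1:100], tolerance = 1e-5)
  expect_equal(z$config$trap$sample_rate, 3000, tolerance = 1e-3)
})
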