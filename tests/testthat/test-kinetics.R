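test_that("rebinding times are gaps between consecutive events", {
  ev <- data.frame(t_start = c(0.5, 1.5, 4), t_end = c(1.0, 2.0, 4.3),
                   truncated = FALSE)
  expect_equal(rebinding_times(ev), c(0.5, 2.0))
  expect_identical(rebinding_times(ev[1, ]), numeric(0))
  bad <- data.frame(t_start = c(0.5, 0.8), t_end = c(1.0, 1.2))
  expect_error(rebinding_times(bad), class = "trapkin_event_error")
})

test_that("true rebinding intervals average 1/k for a constant on-rate", {
  # exponential-sampling oracle: waiting times at constant rate k
  k <- 2
  x <- simulate_trace(trap_config(),
                      dither_config(),
                      motor_model(on_rate_model = on_rate_constant(k),
                                  off_rate_unloaded = 4),
                      d_B_MT = 20, duration = 120, seed = 55)
  te <- x$true_events
  gaps <- te$bind_time[-1] - te$unbind_time[-nrow(te)]
  expect_gt(length(gaps), 80)
  se <- sd(gaps) / sqrt(length(gaps))
  expect_lt(abs(mean(gaps) - 1 / k), 2 * se)
})

test_that("rate and time conversions are exact reciprocals", {
  expect_equal(round(time_from_rate(4.7), 2), 0.21)
  expect_equal(round(time_from_rate(0.71), 1), 1.4)
  expect_equal(round(time_from_rate(1.03), 2), 0.97)
  for (x in c(0.01, 0.33, 1, 4.7, 100)) {
    expect_identical(rate_from_mean_time(time_from_rate(x)), x)
  }
  expect_error(time_from_rate(0), class = "trapkin_config_error")
  expect_error(rate_from_mean_time(-1), class = "trapkin_config_error")
})

test_that("event statistics satisfy the reciprocal identity and handle empties", {
  ev <- data.frame(t_start = c(1, 3, 6), t_end = c(1.4, 3.5, 6.2),
                   bound_time = c(0.4, 0.5, 0.2), peak_force = c(2, 3, 1.5),
                   truncated = c(FALSE, FALSE, FALSE))
  s <- event_statistics(ev)
  expect_equal(s$rebinding_rate * s$mean_rebinding_time, 1)
  expect_identical(s$n_events, 3L)
  empty <- ev[0, ]
  s0 <- event_statistics(empty)
  expect_true(is.na(s0$mean_rebinding_time))
  expect_true(is.na(s0$rebinding_rate))
})

test_that("sweep summaries recover the distance trend and are reproducible", {
  rates <- on_rate_exponential(2, 25)
  mo <- motor_model("K560", on_rate_model = rates, off_rate_unloaded = 3)
  sw <- generate_sweep(trap_config(), dither_config(TRUE, 20, 200), mo,
                       d_values = c(0, 20, 40), reps = 2, duration = 60,
                       seed = 77)
  res <- summarize_sweep(sw, mode = "truth")
  tab <- res$table
  rb <- tab[tab$statistic == "rebinding_time", ]
  rb <- rb[order(rb$d_B_MT), ]
  # on-rate strictly decreasing in d: mean rebinding time increasing
  expect_true(all(diff(rb$value) > 0))
  res2 <- summarize_sweep(sw, mode = "truth")
  expect_identical(res$table, res2$table)
  # detected-mode table carries peak forces and bound times per cell
  det <- summarize_sweep(sw, detection_config())
  expect_setequal(unique(det$table$statistic),
                  c("rebinding_time", "bound_time", "peak_force", "rebinding_rate"))
})

test_that("histograms conserve counts and align the first bin at 1/f", {
  s <- list(rebinding_times = c(0.02, 0.04, 0.3, 0.6, 1.4),
            bound_times = c(0.1, 0.2, 0.35))
  class(s) <- "event_statistics"
  h <- histogram_summaries(s, dither_frequency = 20)
  expect_equal(sum(h$rebinding_time$counts), 5)
  expect_equal(sum(h$bound_time$counts), 3)
  expect_equal(h$rebinding_time$breaks[2] - h$rebinding_time$breaks[1], 1 / 20)
  # direct counting oracle on a constructed mixture
  expect_equal(h$rebinding_time$counts[1], 2)  # the two sub-1/f intervals
  s_empty <- list(rebinding_times = numeric(0), bound_times = numeric(0))
  class(s_empty) <- "event_statistics"
  h0 <- histogram_summaries(s_empty, bin_width = 0.1)
  expect_length(h0$rebinding_time$counts, 0)
  expect_error(histogram_summaries(s, bin_width = 0),
               class = "trapkin_config_error")
})
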