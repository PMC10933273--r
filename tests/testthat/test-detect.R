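test_that("low-pass filter preserves level and attenuates as specified", {
  fs <- 3000
  n <- 6000
  t <- (seq_len(n) - 1) / fs
  for (type in c("fft", "boxcar")) {
    # constant series unchanged
    expect_equal(smooth_trace(rep(2.5, n), 40, type, sample_rate = fs),
                 rep(2.5, n), tolerance = 1e-9)
    # mean preserved
    x <- sin(2 * pi * 3 * t) + rnorm(n, 0, 0.3) + 0.7
    expect_equal(mean(smooth_trace(x, 40, type, sample_rate = fs)), mean(x),
                 tolerance = 1e-2 * sd(x))
    # spectral-ratio oracle: amplitude in/out at a pure tone (cosine phase so
    # the Nyquist tone samples as the alternating +-1 sequence)
    atten <- function(freq) {
      s <- cos(2 * pi * freq * t)
      y <- smooth_trace(s, 40, type, sample_rate = fs)
      core <- 500:(n - 500)
      sqrt(mean(y[core]^2) / mean(s[core]^2))
    }
    expect_lt(atten(fs / 2), 0.1)   # Nyquist: > 90% attenuation
    expect_gt(atten(1), 0.95)       # 1 Hz passes nearly untouched
  }
  expect_error(smooth_trace(rnorm(10), 40, sample_rate = fs),
               class = "trapkin_filter_error")
})

test_that("threshold and dwell criteria score constructed pulses exactly", {
  fs <- 3000
  cfg <- detection_config()
  zero <- rep(0, fs)
  expect_identical(nrow(detect_events(zero, cfg, sample_rate = fs)), 0L)
  # 2 pN x 50 ms square pulse: one event with exact bound time and peak
  f <- rep(0, fs)
  f[301:450] <- 2  # 150 samples = 50 ms
  ev <- detect_events(f, cfg, sample_rate = fs, smooth = FALSE)
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$bound_time, 0.050)
  expect_equal(ev$peak_force, 2)
  expect_equal(ev$t_start, 300 / fs)
  # 5 ms pulse fails the dwell gate
  g <- rep(0, fs)
  g[301:315] <- 2
  expect_identical(nrow(detect_events(g, cfg, sample_rate = fs, smooth = FALSE)), 0L)
  # negative-going event is caught with polarity -1
  ev_neg <- detect_events(-f, cfg, sample_rate = fs, smooth = FALSE)
  expect_identical(ev_neg$polarity, -1L)
})

test_that("event scan agrees with the brute-force rescan oracle", {
  fs <- 3000
  cfg <- detection_config()
  set.seed(31)
  for (i in 1:200) {
    f <- random_force_series(600, 1 / fs)
    fsm <- smooth_trace(f, cfg$filter_points, cfg$filter_type, sample_rate = fs)
    ours <- detect_events(f, cfg, sample_rate = fs)
    oracle <- oracle_rescan(fsm, 1 / fs, cfg$force_threshold, cfg$min_duration)
    expect_identical(nrow(ours), nrow(oracle))
    if (nrow(ours)) {
      expect_equal(ours$t_start, oracle$t_start)
      expect_equal(ours$bound_time, oracle$bound_time)
      expect_equal(ours$peak_force, oracle$peak_force)
    }
  }
})

test_that("raising the dwell gate never adds events; raising the threshold
           only keeps nested sub-intervals", {
  fs <- 3000
  set.seed(32)
  for (i in 1:30) {
    f <- random_force_series(900, 1 / fs)
    base <- detect_events(f, detection_config(), sample_rate = fs)
    n_hi_dwell <- nrow(detect_events(f, detection_config(min_duration = 0.03),
                                     sample_rate = fs))
    expect_lte(n_hi_dwell, nrow(base))
    # a higher threshold can split one long excursion into several events,
    # but every event it reports must nest inside a base above-threshold
    # interval (dwell gate off on the base for strict nesting)
    hi <- detect_events(f, detection_config(force_threshold = 1.5),
                        sample_rate = fs)
    runs <- detect_events(f, detection_config(force_threshold = 1,
                                              min_duration = 0),
                          sample_rate = fs)
    if (nrow(hi)) {
      nested <- vapply(seq_len(nrow(hi)), function(j)
        any(runs$t_start <= hi$t_start[j] & runs$t_end >= hi$t_end[j]),
        logical(1))
      expect_true(all(nested))
    }
  }
})

test_that("dithered detection needs a dither and ignores quiet traces", {
  still <- simulate_trace(trap_config(), dither_config(),
                          motor_model(on_rate_model = on_rate_constant(0)),
                          duration = 1, seed = 1)
  expect_error(detect_events_dithered(still), class = "trapkin_mode_error")
  quiet <- simulate_trace(trap_config(), dither_config(TRUE, 20, 200),
                          motor_model(on_rate_model = on_rate_constant(0)),
                          duration = 5, seed = 2)
  expect_identical(nrow(detect_events_dithered(quiet)), 0L)
})

test_that("a 60 ms event at 20 Hz dither is detected with small latency", {
  x <- simulate_trace(trap_config(temperature = 0), dither_config(TRUE, 20, 200),
                      motor_model("K560"), d_B_MT = 20, duration = 3, seed = 4,
                      scripted_events = data.frame(bind_time = 1.23,
                                                   duration = 0.06))
  ev <- detect_events_dithered(x)
  m <- evaluate_detection(ev, x$true_events)
  expect_equal(m$sensitivity, 1)
  # latency bound: one dither period plus one filter window
  expect_lt(m$mean_latency, 1 / 20 + 40 / 3000)
})

test_that("dithering detects a walking motor about 0.1 s before a stationary trap", {
  trap <- trap_config(temperature = 0)
  motor <- motor_model("K560")
  sc <- data.frame(bind_time = 1.111, duration = 0.5)
  x_st <- simulate_trace(trap, dither_config(), motor, d_B_MT = 20,
                         duration = 3, seed = 6, scripted_events = sc)
  x_di <- simulate_trace(trap, dither_config(TRUE, 20, 200), motor, d_B_MT = 20,
                         duration = 3, seed = 6, scripted_events = sc)
  lat_st <- evaluate_detection(detect_events(x_st), x_st$true_events)$mean_latency
  lat_di <- evaluate_detection(detect_events_dithered(x_di),
                               x_di$true_events)$mean_latency
  # stationary latency matches the tether-travel oracle
  oracle <- oracle_stationary_latency(motor, trap, 20)
  expect_equal(lat_st, oracle, tolerance = 0.25)
  gain <- lat_st - lat_di
  expect_gt(gain, 0.05)
  expect_lt(gain, 0.15)
})

test_that("detection metrics report sensitivity, false positives and latency", {
  truth <- data.frame(bind_time = c(1, 3, 5), unbind_time = c(1.5, 3.2, 5.4))
  perfect <- data.frame(t_start = truth$bind_time, t_end = truth$unbind_time)
  m <- evaluate_detection(perfect, truth)
  expect_equal(m$sensitivity, 1)
  expect_identical(m$false_positives, 0L)
  expect_equal(m$mean_latency, 0)
  empty <- data.frame(t_start = numeric(0), t_end = numeric(0))
  m0 <- evaluate_detection(empty, truth)
  expect_equal(m0$sensitivity, 0)
})
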