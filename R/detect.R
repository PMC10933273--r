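# Force-trace binding-event detection: low-pass filtering, 1 pN threshold
# with a 10 ms dwell gate, stationary and dithered-trap modes.

#' Low-pass filter a force series
#'
#' `"fft"` removes frequency components above `sample_rate / filter_points`
#' (75 Hz for 40 points at 3 kHz) in the frequency domain, on a
#' reflection-padded copy to suppress edge wraparound; `"boxcar"` is a plain
#' `filter_points`-sample centred moving average. Both preserve the series
#' length and mean.
#'
#' @param x A `force_trace` or a numeric force series.
#' @param filter_points Filter width in samples.
#' @param filter_type `"fft"` or `"boxcar"`.
#' @param sample_rate Sampling rate in Hz (taken from the trace when given).
#' @return Numeric filtered series of the same length.
#' @export
smooth_trace <- function(x, filter_points = 40, filter_type = c("fft", "boxcar"),
                         sample_rate = NULL) {
  filter_type <- match.arg(filter_type)
  if (inherits(x, "force_trace")) {
    sample_rate <- x$config$trap$sample_rate
    x <- x$force
  }
  n <- length(x)
  if (filter_points > n)
    abort_runtime("trace shorter than the filter width", "trapkin_filter_error")
  if (filter_points <= 1) return(x)

  if (filter_type == "boxcar") {
    k <- filter_points
    cs <- cumsum(c(0, x))
    half_lo <- floor((k - 1) / 2); half_hi <- k - 1 - half_lo
    lo <- pmax(seq_len(n) - half_lo, 1)
    hi <- pmin(seq_len(n) + half_hi, n)
    return((cs[hi + 1] - cs[lo]) / (hi - lo + 1))
  }

  if (is.null(sample_rate)) sample_rate <- 1
  # reflect-pad to avoid circular wraparound, then brick-wall low pass;
  # total length taken to the next 5-smooth number so the mixed-radix FFT
  # stays fast on long traces
  pad <- min(n, 4 * filter_points)
  pad_right <- pad
  target <- stats::nextn(n + pad + pad_right, c(2, 3, 5))
  if (target - n - pad <= n) pad_right <- target - n - pad
  xp <- c(rev(x[seq_len(pad)]), x, rev(x[(n - pad_right + 1):n]))
  np <- length(xp)
  cutoff <- sample_rate / filter_points
  freq <- (seq_len(np) - 1) / np * sample_rate
  freq <- pmin(freq, sample_rate - freq)  # two-sided
  ft <- stats::fft(xp)
  ft[freq > cutoff] <- 0
  Re(stats::fft(ft, inverse = TRUE))[pad + seq_len(n)] / np
}

# maximal runs where cond is TRUE; returns start/end indices
true_runs <- function(cond) {
  r <- rle(cond)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# assemble the events table from index runs
build_events <- function(runs, time, fsm, dt, cfg, mode, n) {
  if (nrow(runs) == 0) {
    ev <- data.frame(t_start = numeric(0), t_end = numeric(0),
                     bound_time = numeric(0), peak_force = numeric(0),
                     polarity = integer(0), mode = character(0),
                     truncated = logical(0))
    return(structure(ev, class = c("binding_events", "data.frame"), config = cfg))
  }
  peak <- mapply(function(s, e) max(abs(fsm[s:e])), runs$start, runs$end)
  pol <- mapply(function(s, e) {
    m <- fsm[s:e][which.max(abs(fsm[s:e]))]
    as.integer(sign(m))
  }, runs$start, runs$end)
  ev <- data.frame(t_start = time[runs$start],
                   t_end = time[runs$end] + dt,
                   bound_time = (runs$end - runs$start + 1) * dt,
                   peak_force = peak, polarity = pol, mode = mode,
                   truncated = runs$start == 1 | runs$end == n)
  structure(ev, class = c("binding_events", "data.frame"), config = cfg)
}

#' Detect binding events in a stationary-trap force trace
#'
#' Filters the force, then scores maximal intervals where the absolute force
#' stays at or above `force_threshold` for at least `min_duration` as binding
#' events; detachment is the downward re-crossing of the threshold (the
#' sudden fall of the force towards baseline). Events touching the trace
#' boundaries are flagged `truncated`.
#'
#' @param trace A `force_trace` (or numeric force series with `sample_rate`).
#' @param cfg A [detection_config()].
#' @param sample_rate Sampling rate when `trace` is a bare numeric series.
#' @param smooth If `FALSE` the force is thresholded unfiltered.
#' @return A `binding_events` data frame: `t_start`, `t_end`, `bound_time`,
#'   `peak_force`, `polarity`, `mode`, `truncated`.
#' @export
detect_events <- function(trace, cfg = detection_config(), sample_rate = NULL,
                          smooth = TRUE) {
  if (inherits(trace, "force_trace")) {
    sample_rate <- trace$config$trap$sample_rate
    force <- trace$force
    time <- trace$time
  } else {
    force <- as.numeric(trace)
    if (is.null(sample_rate)) abort_config("sample_rate needed for a bare series")
    time <- (seq_along(force) - 1) / sample_rate
  }
  fsm <- if (smooth) smooth_trace(force, cfg$filter_points, cfg$filter_type,
                                  sample_rate = sample_rate) else force
  dt <- 1 / sample_rate
  runs <- true_runs(abs(fsm) >= cfg$force_threshold)
  if (nrow(runs))
    runs <- runs[(runs$end - runs$start + 1) * dt >= cfg$min_duration, ,
                 drop = FALSE]
  build_events(runs, time, fsm, dt, cfg, "stationary", length(force))
}

#' Expected free-bead force response to the commanded dither waveform
#'
#' Deterministic drag-model reference: integrates the noiseless relaxation
#' `dx/dt = -(k/gamma)(x - x_trap(t))` through the commanded trap positions
#' (exact exponential update per sample) and returns the implied force
#' `k (x - x_trap)`. Computed from the waveform alone, so a binding event
#' cannot contaminate the reference.
#'
#' @param trap_position Commanded trap positions, nm.
#' @param trap A [trap_config()].
#' @return Expected free-bead force, pN.
#' @export
expected_dither_response <- function(trap_position, trap) {
  gamma <- drag_coefficient(trap$bead_diameter, trap$viscosity)
  tau <- gamma / trap$stiffness
  a <- exp(-1 / (trap$sample_rate * tau))
  x <- stats::filter((1 - a) * trap_position, a, method = "recursive",
                     init = trap_position[1])
  trap$stiffness * (as.numeric(x) - trap_position)
}

#' Detect binding events in a dithered-trap force trace
#'
#' Subtracts the expected free-bead response to the commanded triangular
#' waveform; a tethered bead stops following the trap, so binding shows up as
#' residual force. The residual is filtered and thresholded with the same
#' dwell gate as the stationary detector; because a bound tether is stretched
#' once per dither half-period, above-threshold excursions separated by less
#' than one dither period are merged into a single event. All true events
#' lasting at least `1/frequency` are detected on noiseless input.
#'
#' @param trace A `force_trace` recorded (or simulated) with a known
#'   commanded dither waveform.
#' @param cfg A [detection_config()].
#' @param dither The [dither_config()]; defaults to the trace's.
#' @return A `binding_events` data frame (`mode = "dithered"`).
#' @export
detect_events_dithered <- function(trace, cfg = detection_config(),
                                   dither = NULL) {
  stopifnot(inherits(trace, "force_trace"))
  if (is.null(dither)) dither <- trace$config$dither
  if (!dither$enabled)
    abort_runtime("trace has no dither; use detect_events() for a stationary trap",
                  "trapkin_mode_error")
  trap <- trace$config$trap
  resid <- trace$force - expected_dither_response(trace$trap_position, trap)
  rsm <- smooth_trace(resid, cfg$filter_points, cfg$filter_type,
                      sample_rate = trap$sample_rate)
  dt <- 1 / trap$sample_rate
  runs <- true_runs(abs(rsm) >= cfg$force_threshold)
  # merge excursions closer than one dither period: one tether, one event
  gap <- 1 / dither$frequency
  if (nrow(runs) > 1) {
    gaps <- (runs$start[-1] - runs$end[-nrow(runs)]) * dt
    grp <- cumsum(c(1L, as.integer(gaps >= gap)))
    runs <- data.frame(
      start = as.integer(tapply(runs$start, grp, min)),
      end = as.integer(tapply(runs$end, grp, max)))
  }
  if (nrow(runs))
    runs <- runs[(runs$end - runs$start + 1) * dt >= cfg$min_duration, ,
                 drop = FALSE]
  build_events(runs, trace$time, rsm, dt, cfg, "dithered", length(resid))
}

#' Compare detected events with ground truth
#'
#' Matches detected events to true bound intervals by interval overlap and
#' reports sensitivity, false positives and detection latencies (detected
#' start minus true bind time).
#'
#' @param events A `binding_events` table.
#' @param true_events Data frame with `bind_time` and `unbind_time`.
#' @param min_true_duration Only true events at least this long (s) count
#'   towards sensitivity (0 = all).
#' @return A list: `n_true`, `n_detected`, `n_matched`, `sensitivity`,
#'   `false_positives`, `latency` (per matched true event, s),
#'   `mean_latency`.
#' @export
evaluate_detection <- function(events, true_events, min_true_duration = 0) {
  te <- true_events[true_events$unbind_time - true_events$bind_time >=
                      min_true_duration, , drop = FALSE]
  n_true <- nrow(te); n_det <- nrow(events)
  if (n_true == 0 || n_det == 0) {
    return(list(n_true = n_true, n_detected = n_det, n_matched = 0L,
                sensitivity = if (n_true) 0 else NA_real_,
                false_positives = n_det,
                latency = numeric(0), mean_latency = NA_real_))
  }
  ov <- outer(seq_len(n_true), seq_len(n_det), function(i, j) {
    pmin(te$unbind_time[i], events$t_end[j]) -
      pmax(te$bind_time[i], events$t_start[j])
  })
  matched <- apply(ov > 0, 1, any)
  det_matched <- apply(ov > 0, 2, any)
  first_det <- vapply(which(matched), function(i) {
    j <- which(ov[i, ] > 0)
    min(events$t_start[j])
  }, numeric(1))
  latency <- first_det - te$bind_time[matched]
  list(n_true = n_true, n_detected = n_det,
       n_matched = sum(matched),
       sensitivity = mean(matched),
       false_positives = sum(!det_matched),
       latency = latency,
       mean_latency = if (length(latency)) mean(latency) else NA_real_)
}
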