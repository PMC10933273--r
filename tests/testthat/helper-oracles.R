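# Independent oracles and fixture builders used across the suite.

# Brute-force threshold/dwell re-scan of a force series: an explicit loop,
# deliberately independent of the package's run-length implementation.
oracle_rescan <- function(f, dt, threshold, min_duration) {
  above <- abs(f) >= threshold
  n <- length(f)
  out <- list()
  i <- 1
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1]) j <- j + 1
      if ((j - i + 1) * dt >= min_duration)
        out[[length(out) + 1]] <- data.frame(
          t_start = (i - 1) * dt, t_end = j * dt,
          bound_time = (j - i + 1) * dt,
          peak_force = max(abs(f[i:j])))
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(t_start = numeric(0), t_end = numeric(0),
                  bound_time = numeric(0), peak_force = numeric(0))
}

# random piecewise force series: plateaus of random level/length plus noise,
# exercising crossings near the threshold and the dwell gate
random_force_series <- function(n = 600, dt = 1 / 3000) {
  n_seg <- sample(3:10, 1)
  lens <- as.vector(stats::rmultinom(1, n, rep(1, n_seg)))
  level <- stats::runif(n_seg, -2.5, 2.5)
  f <- rep(level, lens)[seq_len(n)]
  f + stats::rnorm(n, 0, 0.15)
}

# brute-force lattice enumeration for the reach model, independent of
# accessible_sites()
oracle_site_count <- function(d, tether, period, window, offset = 0) {
  m <- ceiling(2 * window / period)
  xs <- offset + (-m:m) * period
  xs <- xs[abs(xs) <= window]
  sum(sqrt(xs^2 + d^2) <= tether)
}

# stationary-trap detection latency oracle: the motor must walk through the
# projected tether slack, stretch the tether by F/k_tether and displace the
# bead by F/k_trap before the force reaches threshold; speed is bounded by
# the unloaded speed
oracle_stationary_latency <- function(motor, trap, d_B_MT, threshold = 1) {
  slack <- sqrt(max(motor$tether_length^2 - d_B_MT^2, 0))
  travel <- slack + threshold / motor$tether_stiffness + threshold / trap$stiffness
  travel / motor$speed_unloaded
}
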