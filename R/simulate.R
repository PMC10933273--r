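# Stochastic generator of optical-trap force traces: overdamped Langevin
# bead motion in a (possibly dithered) harmonic trap, with distance-dependent
# motor binding, load-dependent walking and Bell-type detachment.

# commanded trap waveform, nm, at the given times
trap_waveform <- function(times, dither) {
  if (!dither$enabled) return(rep(0, length(times)))
  amp <- dither$peak_to_peak / 2
  phase <- (times * dither$frequency) %% 1
  # triangle starting at 0, rising: 0 -> +A -> -A -> 0 per period
  amp * ifelse(phase < 0.25, 4 * phase,
               ifelse(phase < 0.75, 2 - 4 * phase, 4 * phase - 4))
}

# substep sizes obeying dt <= safety * relaxation time (gamma/stiffness),
# with the tether's stiffness included while bound
langevin_substeps <- function(trap, motor, internal_dt = NULL, safety = 0.1) {
  gamma <- drag_coefficient(trap$bead_diameter, trap$viscosity)
  dt_u_max <- safety * gamma / trap$stiffness
  dt_b_max <- safety * gamma / (trap$stiffness + motor$tether_stiffness)
  if (!is.null(internal_dt)) {
    if (internal_dt > dt_u_max)
      abort_runtime(sprintf(
        "internal_dt = %g s is too coarse for stability: need <= %g s (%g x gamma/k)",
        internal_dt, dt_u_max, safety), "trapkin_stability_error")
    dt_u_max <- internal_dt
    dt_b_max <- min(dt_b_max, internal_dt)
  }
  dt_out <- 1 / trap$sample_rate
  list(dt_unbound = dt_out / ceiling(dt_out / dt_u_max),
       dt_bound = dt_out / ceiling(dt_out / dt_b_max),
       gamma = gamma)
}

#' Simulate an optical-trap force trace
#'
#' Integrates the overdamped Langevin equation for the trapped bead (thermal
#' noise satisfying fluctuation-dissipation), with a single motor that binds
#' the microtubule as a Poisson process at rate `motor$on_rate_model(d_B_MT)`
#' (zero whenever no lattice site is within tether reach), walks at a
#' load-dependent speed (linear force-velocity to stall), pulls the bead
#' through a tether that is slack below its rest length, and detaches at the
#' Bell rate `off_rate_unloaded * exp(|F| / force_scale_detach)`. The force
#' channel is `stiffness * (bead_position - trap_position)`, as read by a
#' position-sensitive detector. Output is decimated to `trap$sample_rate`
#' from a finer internal step, so the sampled bead motion keeps the exact
#' Ornstein-Uhlenbeck statistics.
#'
#' @param trap A [trap_config()].
#' @param dither A [dither_config()].
#' @param motor A [motor_model()].
#' @param d_B_MT Bead-surface to microtubule-surface gap, nm.
#' @param duration Trace duration, s.
#' @param seed Integer RNG seed (identical inputs + seed give an identical
#'   trace).
#' @param scripted_events Optional data frame with columns `bind_time` and
#'   `duration` (s): binding then occurs exactly at those times instead of
#'   stochastically, for detector validation.
#' @param internal_dt Optional internal time step override, s; an explicit
#'   stability error is raised if it exceeds one tenth of the bead relaxation
#'   time.
#' @return A `force_trace`: time, force (pN), trap/bead positions (nm),
#'   per-sample ground-truth `motor_bound` flags, the `true_events` table
#'   (bind/unbind times, truncation flags) and a config snapshot.
#' @export
simulate_trace <- function(trap = trap_config(), dither = dither_config(),
                           motor = motor_model(), d_B_MT = 20,
                           duration = 10, seed = 1,
                           scripted_events = NULL, internal_dt = NULL) {
  stopifnot(inherits(trap, "trap_config"), inherits(dither, "dither_config"),
            inherits(motor, "motor_model"))
  if (!is.numeric(duration) || duration <= 0)
    abort_config("duration must be > 0 (s)")
  if (d_B_MT < 0) abort_config("d_B_MT must be >= 0 (nm)")
  if (is.null(seed) || !is.finite(seed)) abort_config("seed must be given")

  n <- max(2L, as.integer(round(duration * trap$sample_rate)))
  dt_out <- 1 / trap$sample_rate
  times <- (seq_len(n) - 1) * dt_out
  trap_pos <- trap_waveform(times, dither)
  ss <- langevin_substeps(trap, motor, internal_dt)
  kT <- thermal_energy(trap$temperature)

  # geometry gate: no binding when the motor cannot reach any site
  geom <- reach_geometry(d_B_MT, motor$tether_length)
  k_on <- if (accessible_sites(geom) >= 1) motor$on_rate_model(d_B_MT) else 0
  if (!is.finite(k_on) || k_on < 0) abort_config("on_rate_model returned an invalid rate")
  # tether slack projected onto the microtubule axis at this height
  slack <- sqrt(max(motor$tether_length^2 - d_B_MT^2, 0))

  sb <- numeric(0); sd_ <- numeric(0)
  if (!is.null(scripted_events)) {
    stopifnot(all(c("bind_time", "duration") %in% names(scripted_events)))
    o <- order(scripted_events$bind_time)
    sb <- as.numeric(scripted_events$bind_time[o])
    sd_ <- as.numeric(scripted_events$duration[o])
    if (any(sd_ <= 0)) abort_config("scripted event durations must be > 0")
    if (any(sb[-1] < sb[-length(sb)] + sd_[-length(sd_)]))
      abort_config("scripted events must not overlap")
  }

  set.seed(as.integer(seed))
  x0 <- trap_pos[1] + if (kT > 0) stats::rnorm(1, 0, sqrt(kT / trap$stiffness)) else 0
  res <- langevin_core(trap_pos, dt_out,
                       trap$stiffness, ss$gamma, kT,
                       k_on, motor$speed_unloaded, motor$stall_force,
                       motor$off_rate_unloaded, motor$force_scale_detach,
                       slack, motor$tether_stiffness,
                       geom$lattice_period,
                       ss$dt_unbound, ss$dt_bound,
                       sb, sd_, x0)

  nb <- length(res$bind_times)
  truncated <- rep(FALSE, nb)
  if (nb > 0 && res$bound[n]) truncated[nb] <- TRUE
  true_events <- data.frame(
    bind_time = res$bind_times,
    unbind_time = res$unbind_times[seq_len(nb)],
    truncated = truncated
  )

  structure(list(time = times, force = res$force, trap_position = trap_pos,
                 bead_position = res$bead, motor_bound = res$bound,
                 true_events = true_events,
                 config = list(trap = trap, dither = dither, motor = motor,
                               d_B_MT = d_B_MT, duration = duration,
                               seed = as.integer(seed), k_on = k_on)),
            class = "force_trace")
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf("force_trace: %.3g s at %g Hz, d_B-MT = %g nm, %s, %d true event(s)\n",
              max(x$time) + x$time[2], x$config$trap$sample_rate,
              x$config$d_B_MT,
              if (x$config$dither$enabled)
                sprintf("dithered %g Hz", x$config$dither$frequency)
              else "stationary trap",
              nrow(x$true_events)))
  invisible(x)
}

#' @export
summary.force_trace <- function(object, ...) {
  ev <- object$true_events
  out <- list(duration = max(object$time) + object$time[2],
              d_B_MT = object$config$d_B_MT,
              n_events = nrow(ev),
              bound_fraction = mean(object$motor_bound),
              force_sd = stats::sd(object$force),
              bead_var = stats::var(object$bead_position))
  class(out) <- "summary.force_trace"
  out
}

#' @export
print.summary.force_trace <- function(x, ...) {
  cat(sprintf(paste0("force_trace summary: %.3g s, d_B-MT %g nm, %d true events, ",
                     "bound fraction %.3f\n  force sd %.3f pN, bead variance %.1f nm^2\n"),
              x$duration, x$d_B_MT, x$n_events, x$bound_fraction,
              x$force_sd, x$bead_var))
  invisible(x)
}

#' @export
as.data.frame.force_trace <- function(x, ...) {
  data.frame(time_s = x$time, force_pN = x$force,
             trap_pos_nm = x$trap_position, bead_pos_nm = x$bead_position,
             motor_bound = x$motor_bound)
}

#' @export
plot.force_trace <- function(x, which = c("force", "position"), ...) {
  which <- match.arg(which)
  if (which == "force") {
    plot(x$time, x$force, type = "l", xlab = "time (s)", ylab = "force (pN)",
         col = "grey30", ...)
    if (nrow(x$true_events))
      graphics::rect(x$true_events$bind_time, graphics::par("usr")[3],
                     x$true_events$unbind_time, graphics::par("usr")[4],
                     col = grDevices::adjustcolor("indianred", 0.2), border = NA)
  } else {
    plot(x$time, x$bead_position, type = "l", xlab = "time (s)",
         ylab = "position (nm)", col = "grey30", ...)
    graphics::lines(x$time, x$trap_position, col = "steelblue")
  }
  invisible(x)
}

#' Generate a sweep of traces over distances and constructs
#'
#' One trace per (distance, construct, repeat) cell, with deterministic
#' per-cell sub-seeds drawn from the master seed, emulating the assay design
#' of stepping the stage through separations 0-70.4 nm in 17.6 nm increments
#' for each motor construct.
#'
#' @param trap,dither Shared [trap_config()] / [dither_config()].
#' @param motors A single [motor_model()] or a (possibly named) list of them.
#' @param d_values Vector of bead-microtubule separations, nm.
#' @param reps Repeats per cell.
#' @param duration Duration of each trace, s.
#' @param seed Master seed; sub-seeds are `sample.int(2^31 - 2, n)` drawn
#'   once from it, indexed in cell order.
#' @return A `trace_sweep`: list of `force_trace` objects with a `cells`
#'   metadata table (d_B_MT, construct, rep, seed).
#' @export
generate_sweep <- function(trap = trap_config(), dither = dither_config(),
                           motors = motor_model(),
                           d_values = corrected_distance(seq(0, 80, by = 20), 0.12),
                           reps = 1, duration = 10, seed = 1) {
  if (length(d_values) == 0) abort_config("d_values must be non-empty")
  if (any(d_values < 0)) abort_config("d_values must be >= 0")
  if (reps < 0 || reps != round(reps)) abort_config("reps must be a non-negative integer")
  if (inherits(motors, "motor_model")) motors <- list(motors)
  if (!length(motors) || !all(vapply(motors, inherits, TRUE, "motor_model")))
    abort_config("motors must be motor_model objects")
  names(motors) <- vapply(seq_along(motors), function(i) {
    nm <- names(motors)[i]
    if (!is.null(nm) && nzchar(nm)) nm else motors[[i]]$construct
  }, character(1))

  cells <- expand.grid(rep = seq_len(reps), d_B_MT = d_values,
                       construct = names(motors),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (nrow(cells) == 0) {
    return(structure(list(traces = list(),
                          cells = cbind(cells, seed = integer(0)),
                          seed = seed),
                     class = "trace_sweep"))
  }
  set.seed(as.integer(seed))
  cells$seed <- sample.int(2^31 - 2, nrow(cells))
  traces <- lapply(seq_len(nrow(cells)), function(i) {
    simulate_trace(trap, dither, motors[[cells$construct[i]]],
                   d_B_MT = cells$d_B_MT[i], duration = duration,
                   seed = cells$seed[i])
  })
  structure(list(traces = traces, cells = cells, seed = seed),
            class = "trace_sweep")
}

#' @export
print.trace_sweep <- function(x, ...) {
  cat(sprintf("trace_sweep: %d trace(s); %d distance(s) x %d construct(s) x %d rep(s)\n",
              length(x$traces), length(unique(x$cells$d_B_MT)),
              length(unique(x$cells$construct)),
              if (nrow(x$cells)) max(x$cells$rep) else 0))
  invisible(x)
}

#' Inject slow stage drift into a z-trajectory
#'
#' Adds a linear drift plus a Brownian random walk to a stage z-trajectory,
#' emulating the slow thermal/mechanical drift that the focus lock must
#' correct. The ground-truth drift is returned for controller validation.
#'
#' @param times Time grid, s (or a single duration with `dt` given).
#' @param drift_rate Linear drift rate, nm/s.
#' @param diffusion Random-walk diffusion coefficient, nm^2/s (0 for purely
#'   linear drift).
#' @param seed RNG seed.
#' @param z0 Starting z, nm.
#' @param dt Sample interval when `times` is a duration, s.
#' @return A data frame with `time`, `z` (drifted trajectory) and
#'   `drift` (ground-truth displacement from `z0`).
#' @export
inject_drift <- function(times, drift_rate = 0, diffusion = 0, seed = 1,
                         z0 = 0, dt = 0.04) {
  if (!is.finite(drift_rate)) abort_config("drift_rate must be finite")
  if (diffusion < 0) abort_config("diffusion must be >= 0")
  if (length(times) == 1) times <- seq(0, times, by = dt)
  set.seed(as.integer(seed))
  steps <- diff(times)
  walk <- if (diffusion > 0)
    c(0, cumsum(stats::rnorm(length(steps), 0, sqrt(2 * diffusion * steps))))
  else rep(0, length(times))
  drift <- drift_rate * (times - times[1]) + walk
  data.frame(time = times, z = z0 + drift, drift = drift)
}
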