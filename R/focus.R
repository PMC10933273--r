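# Simulated template-match focus lock: defocused-bead image synthesis,
# 0-1000 match scoring, score-slope calibration, a 1 s drift-correction loop,
# and surface identification from the trapped-bead score.

#' Render a synthetic defocused-bead image
#'
#' Radially symmetric intensity pattern of a fiduciary bead on a 40 x 40
#' pixel grid: a Gaussian spot whose blur radius grows with |defocus|
#' (point-spread proxy), normalised so that blur redistributes rather than
#' creates light, plus optional additive noise.
#'
#' @param defocus Axial offset from the focal plane, nm.
#' @param noise_level Additive Gaussian noise, as a fraction of the in-focus
#'   peak intensity.
#' @param seed RNG seed (`NULL` to use the current RNG state).
#' @param size Image side, pixels.
#' @param pixel_size Pixel pitch, nm.
#' @param spot_sigma In-focus spot width, pixels.
#' @param defocus_scale Defocus scale over which the blur doubles in
#'   quadrature, nm.
#' @return A `bead_image` (fields `pixels`, `defocus`, `pixel_size`).
#' @export
render_bead_image <- function(defocus, noise_level = 0.02, seed = NULL,
                              size = 40, pixel_size = 100, spot_sigma = 2,
                              defocus_scale = 300) {
  if (noise_level < 0) abort_config("noise_level must be >= 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  sigma <- spot_sigma * sqrt(1 + (defocus / defocus_scale)^2)
  c0 <- (size + 1) / 2
  ax <- seq_len(size) - c0
  r2 <- outer(ax^2, ax^2, `+`)
  total <- 1000  # arbitrary integrated intensity, conserved across defocus
  px <- total * exp(-r2 / (2 * sigma^2)) / (2 * pi * sigma^2)
  if (noise_level > 0) {
    peak0 <- total / (2 * pi * spot_sigma^2)
    px <- px + matrix(stats::rnorm(size^2, 0, noise_level * peak0), size, size)
    px[px < 0] <- 0
  }
  structure(list(pixels = px, defocus = defocus, pixel_size = pixel_size),
            class = "bead_image")
}

#' @export
print.bead_image <- function(x, ...) {
  cat(sprintf("bead_image: %d x %d px, defocus %g nm, total intensity %.4g\n",
              nrow(x$pixels), ncol(x$pixels), x$defocus, sum(x$pixels)))
  invisible(x)
}

#' @export
plot.bead_image <- function(x, ...) {
  graphics::image(x$pixels, asp = 1, axes = FALSE, col = grDevices::gray.colors(64),
                  main = sprintf("defocus %g nm", x$defocus), ...)
  invisible(x)
}

#' Template-match score between two bead images
#'
#' Zero-normalised intensity cross-correlation of the two pixel grids, scaled
#' to the instrument's score range: 1000 is a perfect match, 0 no match.
#' Symmetric in its arguments. Anti-correlated images give negative values;
#' the focus-lock loop clips its reported scores to `[0, 1000]`.
#'
#' @param template,image `bead_image` objects (or bare matrices) of equal
#'   shape.
#' @param clip Clip the result to `[0, 1000]`?
#' @return Score in `[-1000, 1000]` (or `[0, 1000]` when clipped).
#' @export
match_score <- function(template, image, clip = FALSE) {
  a <- if (inherits(template, "bead_image")) template$pixels else template
  b <- if (inherits(image, "bead_image")) image$pixels else image
  if (!all(dim(a) == dim(b))) abort_config("images must have equal shapes")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    abort_runtime("constant image: correlation undefined", "trapkin_score_error")
  s <- 1000 * stats::cor(as.vector(a), as.vector(b))
  if (clip) s <- min(max(s, 0), 1000)
  s
}

#' Score-versus-defocus curve for a stored template
#'
#' Renders a noiseless live image at each defocus and scores it against the
#' template. With the operating template recorded ~300 nm out of the focal
#' plane, the curve peaks at 300 nm and is locally quadratic around the peak,
#' with steep, nearly linear flanks near the surface - which is what makes
#' the out-of-focus template a sensitive z sensor.
#'
#' @param defocus_values Defocus grid, nm.
#' @param template A `bead_image` (default: noiseless template at 300 nm).
#' @param ... Passed to [render_bead_image()].
#' @return Data frame with `defocus` and `score`.
#' @export
focus_score_curve <- function(defocus_values,
                              template = render_bead_image(300, noise_level = 0),
                              ...) {
  score <- vapply(defocus_values, function(z)
    match_score(template, render_bead_image(z, noise_level = 0, ...)),
    numeric(1))
  data.frame(defocus = defocus_values, score = score)
}

#' Measurement closure for the focus-lock simulations
#'
#' Returns a function `f(z)` that renders a live image at defocus `z` (with
#' the given noise) and scores it against the template - the simulated
#' camera + pattern-match pipeline.
#'
#' @param template A `bead_image`.
#' @param noise_level Image noise level.
#' @param seed Seed for the live-image noise stream.
#' @return A function of the defocus returning a score.
#' @export
make_score_function <- function(template = render_bead_image(300, noise_level = 0),
                                noise_level = 0, seed = 1) {
  set.seed(as.integer(seed))
  function(z) match_score(template, render_bead_image(z, noise_level = noise_level,
                                                      seed = NULL))
}

#' Focus-lock controller state
#'
#' @param z_stage Current stage z, nm.
#' @param score_setpoint Score the loop maintains ('Score, set').
#' @param slope Calibrated score change per nm (`NA` until calibrated).
#' @param correction_interval Seconds between corrections.
#' @param max_step Largest single correction, nm.
#' @return A `focus_state`.
#' @export
focus_state <- function(z_stage = 0, score_setpoint = NA_real_,
                        slope = NA_real_, correction_interval = 1,
                        max_step = 100) {
  if (correction_interval <= 0) abort_config("correction_interval must be > 0")
  if (max_step <= 0) abort_config("max_step must be > 0")
  structure(list(z_stage = z_stage, score_setpoint = score_setpoint,
                 slope = slope, correction_interval = correction_interval,
                 max_step = max_step, last_correction_time = -Inf),
            class = "focus_state")
}

#' Calibrate the score-per-nm slope
#'
#' Commands a z-excursion (100 nm in the assay) and takes
#' `slope = (score(z + excursion) - score(z)) / excursion`. Fails explicitly
#' when the score change is below the noise floor (e.g. operating exactly at
#' the score vertex, where the curve is flat).
#'
#' @param state A [focus_state()].
#' @param score_fn Measurement function from [make_score_function()].
#' @param excursion Commanded excursion, nm.
#' @param noise_floor Minimum usable |score change|.
#' @return The `focus_state` with `slope` and `score_setpoint` filled in.
#' @export
calibrate_slope <- function(state, score_fn, excursion = 100, noise_floor = 1) {
  stopifnot(inherits(state, "focus_state"))
  s0 <- score_fn(state$z_stage)
  s1 <- score_fn(state$z_stage + excursion)
  if (abs(s1 - s0) < noise_floor)
    abort_runtime(sprintf("score change %.3g below noise floor %.3g: cannot calibrate",
                          abs(s1 - s0), noise_floor), "trapkin_calibration_error")
  state$slope <- (s1 - s0) / excursion
  if (is.na(state$score_setpoint)) state$score_setpoint <- s0
  state
}

#' One drift-correction step
#'
#' Proportional controller with unity loop gain through the calibrated
#' slope: `command = (setpoint - measured) / slope`, clipped to
#' `state$max_step`.
#'
#' @param state A calibrated [focus_state()].
#' @param measured_score Current score.
#' @return Commanded stage move, nm.
#' @export
drift_correction_step <- function(state, measured_score) {
  stopifnot(inherits(state, "focus_state"))
  if (!is.finite(state$slope) || state$slope == 0)
    abort_runtime("focus state is not calibrated", "trapkin_calibration_error")
  cmd <- (state$score_setpoint - measured_score) / state$slope
  min(max(cmd, -state$max_step), state$max_step)
}

#' Run the closed focus-lock loop against a drifting stage
#'
#' Images at `frame_rate` (~25 Hz in the assay), corrections every
#' `state$correction_interval` (1 s). The drift trajectory (e.g. from
#' [inject_drift()]) perturbs the defocus; each correction moves the stage to
#' pull the score back to the setpoint.
#'
#' @param state A calibrated [focus_state()].
#' @param drift Data frame from [inject_drift()] (columns `time`, `drift`).
#' @param score_fn Measurement function; the loop evaluates it at the current
#'   defocus error plus the operating point.
#' @param z_operating Operating defocus of the live bead, nm.
#' @param frame_rate Camera rate, Hz.
#' @param controller_on If `FALSE` the drift is left uncorrected (for paired
#'   comparisons).
#' @return Data frame log: `time`, `score`, `z_error` (true defocus error,
#'   nm), `z_command_nm` (0 between corrections).
#' @export
run_focus_lock <- function(state, drift, score_fn, z_operating = 100,
                           frame_rate = 25, controller_on = TRUE) {
  stopifnot(inherits(state, "focus_state"))
  if (controller_on && (!is.finite(state$slope) || state$slope == 0))
    abort_runtime("focus state is not calibrated", "trapkin_calibration_error")
  times <- drift$time
  correction <- 0
  log_score <- log_err <- log_cmd <- numeric(length(times))
  for (i in seq_along(times)) {
    z_err <- drift$drift[i] + correction
    sc <- score_fn(z_operating + z_err)
    cmd <- 0
    if (controller_on &&
        times[i] - state$last_correction_time >= state$correction_interval) {
      cmd <- drift_correction_step(state, sc)
      correction <- correction + cmd
      state$last_correction_time <- times[i]
    }
    log_score[i] <- sc; log_err[i] <- z_err; log_cmd[i] <- cmd
  }
  data.frame(time = times, score = log_score, z_error = log_err,
             z_command_nm = log_cmd)
}

#' Simulate a trapped-bead surface approach
#'
#' The stage moves the surface up towards the trapped bead in 10 nm steps.
#' While the bead floats free it stays in the focal plane, so its match
#' score is flat; once the surface touches the bead it is pushed out of the
#' focal plane and the score changes with further stage motion.
#'
#' @param contact_z Ground-truth stage z at which the surface reaches the
#'   bead, nm.
#' @param baseline Pre-contact score.
#' @param slope_after Score change per nm of post-contact stage motion.
#' @param noise_sd Score noise per frame.
#' @param seed RNG seed for the score noise.
#' @return A `surface_approach`: function `score(z, n_frames)` plus metadata.
#' @export
simulate_surface_approach <- function(contact_z, baseline = 500,
                                      slope_after = 10, noise_sd = 1,
                                      seed = 1) {
  set.seed(as.integer(seed))
  fun <- function(z, n_frames = 1) {
    mu <- baseline + ifelse(z > contact_z, slope_after * (z - contact_z), 0)
    mu + if (noise_sd > 0) stats::rnorm(n_frames, 0, noise_sd) else rep(0, n_frames)
  }
  structure(list(score = fun, contact_z = contact_z, baseline = baseline,
                 slope_after = slope_after, noise_sd = noise_sd),
            class = "surface_approach")
}

#' Find the surface by stepping the stage towards the trapped bead
#'
#' Raises the stage in `step` nm increments, averaging `frames_per_step`
#' score frames per step. Contact is declared at the first step whose score
#' departs from the running pre-contact baseline by more than a noise-scaled
#' threshold; the contact height is then refined from the measured
#' post-contact slope, so the reported z is within one step of the true
#' contact (exact on noiseless input).
#'
#' @param approach A [simulate_surface_approach()] object (or a function
#'   `score(z, n_frames)`).
#' @param step Approach step, nm.
#' @param z_start First scanned stage position, nm.
#' @param z_max Largest stage position scanned, nm.
#' @param frames_per_step Score frames averaged per step.
#' @param threshold_sd Detection threshold in units of the per-step score
#'   noise.
#' @param noise_sd Per-frame score noise (taken from the approach object when
#'   available).
#' @param refine Refine the contact height from the post-contact slope?
#' @return A list: `z_contact` (reported contact, nm), `z_trigger` (step that
#'   fired), `scores`, `z`, `baseline`, `threshold`.
#' @export
find_surface <- function(approach, step = 10, z_start = 0, z_max = 300,
                         frames_per_step = 25, threshold_sd = 5,
                         noise_sd = NULL, refine = TRUE) {
  score_fn <- if (inherits(approach, "surface_approach")) approach$score
              else approach
  if (is.null(noise_sd))
    noise_sd <- if (inherits(approach, "surface_approach")) approach$noise_sd else 0
  zs <- seq(z_start, z_max, by = step)
  if (length(zs) < 2) abort_config("scan range must cover at least two steps")
  scores <- vapply(zs, function(z) mean(score_fn(z, frames_per_step)), numeric(1))
  thr <- max(threshold_sd * noise_sd / sqrt(frames_per_step) * sqrt(2), 1e-9)
  trigger <- NA_integer_
  for (i in 2:length(zs)) {
    baseline <- mean(scores[seq_len(i - 1)])
    if (abs(scores[i] - baseline) > thr) { trigger <- i; break }
  }
  if (is.na(trigger))
    abort_runtime("no surface contact found within the scan range",
                  "trapkin_surface_error")
  baseline <- mean(scores[seq_len(trigger - 1)])
  z_contact <- zs[trigger]
  if (refine) {
    # estimate the post-contact slope from the steps beyond the trigger and
    # back out the penetration depth at the trigger step
    z_extra <- zs[trigger] + step * seq_len(3)
    s_extra <- vapply(z_extra, function(z) mean(score_fn(z, frames_per_step)),
                      numeric(1))
    slope_est <- mean(diff(c(scores[trigger], s_extra))) / step
    if (is.finite(slope_est) && abs(slope_est) > thr / step) {
      penetration <- (scores[trigger] - baseline) / slope_est
      z_contact <- zs[trigger] - max(min(penetration, step), 0)
    }
  }
  list(z_contact = z_contact, z_trigger = zs[trigger], z = zs,
       scores = scores, baseline = baseline, threshold = thr)
}
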