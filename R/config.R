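# Configuration constructors. Each returns a validated classed list; all
# physical defaults are the assay's operating conditions.

#' Optical trap configuration
#'
#' Describes the trap and detection bandwidth: a polystyrene bead of 0.56 um
#' held in a harmonic trap of stiffness ~0.045 pN/nm, with the position signal
#' (force) sampled at 3 kHz.
#'
#' @param stiffness Trap stiffness k_trap in pN/nm.
#' @param bead_diameter Bead diameter in nm.
#' @param temperature Bath temperature in K.
#' @param sample_rate Output sampling rate of the force channel in Hz.
#' @param viscosity Buffer dynamic viscosity in Pa s.
#' @return An object of class `trap_config`.
#' @export
trap_config <- function(stiffness = 0.045, bead_diameter = 560,
                        temperature = 298, sample_rate = 3000,
                        viscosity = 8.9e-4) {
  if (!is.numeric(stiffness) || length(stiffness) != 1 || !is.finite(stiffness) || stiffness <= 0)
    abort_config("stiffness must be a single positive number (pN/nm)")
  if (!is.numeric(bead_diameter) || bead_diameter <= 0)
    abort_config("bead_diameter must be > 0 (nm)")
  if (!is.numeric(temperature) || temperature < 0)
    abort_config("temperature must be >= 0 (K)")
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    abort_config("sample_rate must be > 0 (Hz)")
  if (!is.numeric(viscosity) || viscosity <= 0)
    abort_config("viscosity must be > 0 (Pa s)")
  structure(list(stiffness = stiffness, bead_diameter = bead_diameter,
                 temperature = temperature, sample_rate = sample_rate,
                 viscosity = viscosity),
            class = "trap_config")
}

#' Trap dithering configuration
#'
#' Periodic triangular translation of the trap along the microtubule axis.
#' A newly formed tether then produces a force signal within one dither
#' period, so events longer than `1/frequency` become detectable.
#'
#' @param enabled Logical; dither the trap?
#' @param frequency Dither frequency in Hz (10 or 20 in the assay).
#' @param peak_to_peak Peak-to-peak trap excursion in nm.
#' @param waveform Waveform type; only `"triangular"` is supported.
#' @return An object of class `dither_config`.
#' @export
dither_config <- function(enabled = FALSE, frequency = 20,
                          peak_to_peak = 200, waveform = "triangular") {
  waveform <- match.arg(waveform, "triangular")
  if (!is.logical(enabled) || length(enabled) != 1 || is.na(enabled))
    abort_config("enabled must be TRUE or FALSE")
  if (enabled && (!is.numeric(frequency) || frequency <= 0))
    abort_config("frequency must be > 0 when dithering is enabled")
  if (!is.numeric(peak_to_peak) || peak_to_peak <= 0)
    abort_config("peak_to_peak must be > 0 (nm)")
  structure(list(enabled = enabled, frequency = frequency,
                 peak_to_peak = peak_to_peak, waveform = waveform),
            class = "dither_config")
}

#' Maximum commanded trap speed of a triangular dither
#'
#' Sweep-rate convention `frequency x peak_to_peak` (20 Hz with a 200 nm
#' peak-to-peak sweep gives 4000 nm/s, i.e. ~4 um/s, comparable to vesicular
#' transport speeds).
#'
#' @param frequency Dither frequency, Hz.
#' @param peak_to_peak Peak-to-peak excursion, nm.
#' @return Speed in nm/s.
#' @export
max_trap_speed <- function(frequency, peak_to_peak = 200) {
  if (frequency <= 0 || peak_to_peak <= 0)
    abort_config("frequency and peak_to_peak must be > 0")
  frequency * peak_to_peak
}

#' Minimum event duration detectable with a dithered trap
#'
#' A dither at frequency f reveals any tether that persists for at least one
#' period, so the detection floor is `1/frequency` seconds.
#'
#' @param frequency Dither frequency, Hz.
#' @return Duration in s.
#' @export
min_detectable_duration <- function(frequency) {
  if (frequency <= 0) abort_config("frequency must be > 0")
  1 / frequency
}

# stalk lengths (nm): coiled-coil rise beyond the ~370 aa motor domain plus
# ~30 nm of antibody/streptavidin linkage; K560 matches the ~60 nm combined
# motor-antibody linkage of the assay
.construct_tethers <- c(DK406 = 35, K560 = 60, DK746 = 85)

#' Motor model
#'
#' Kinetic and mechanical parameters of a single processive motor tethered to
#' the trapped bead. Construct presets set the tether (stalk + antibody
#' linkage) length: truncations at 406, 560 and 746 aa of KIF5B give
#' progressively longer stalks.
#'
#' @param construct One of `"K560"`, `"DK406"`, `"DK746"`, `"custom"`.
#' @param tether_length Combined motor + antibody linkage length, nm.
#'   Defaults from the construct preset.
#' @param speed_unloaded Unloaded walking speed, nm/s.
#' @param stall_force Stall force, pN (linear force-velocity to stall).
#' @param off_rate_unloaded Unloaded detachment rate, 1/s.
#' @param force_scale_detach Bell-model force scale of detachment, pN.
#' @param on_rate_model Function of the bead-microtubule gap d (nm) returning
#'   the binding rate in 1/s; see [on_rate_exponential()],
#'   [on_rate_geometric()], [on_rate_constant()].
#' @param tether_stiffness Stiffness of the tether beyond its rest length,
#'   pN/nm (slack below rest length).
#' @return An object of class `motor_model`.
#' @export
motor_model <- function(construct = c("K560", "DK406", "DK746", "custom"),
                        tether_length = NULL,
                        speed_unloaded = 800,
                        stall_force = 6,
                        off_rate_unloaded = 1,
                        force_scale_detach = 2,
                        on_rate_model = on_rate_exponential(),
                        tether_stiffness = 0.2) {
  construct <- match.arg(construct)
  if (is.null(tether_length)) {
    if (construct == "custom")
      abort_config("tether_length must be given for a custom construct")
    tether_length <- unname(.construct_tethers[construct])
  }
  if (tether_length <= 0) abort_config("tether_length must be > 0 (nm)")
  if (speed_unloaded < 0) abort_config("speed_unloaded must be >= 0")
  if (stall_force <= 0) abort_config("stall_force must be > 0")
  if (off_rate_unloaded < 0) abort_config("off_rate_unloaded must be >= 0")
  if (force_scale_detach <= 0) abort_config("force_scale_detach must be > 0")
  if (!is.function(on_rate_model)) abort_config("on_rate_model must be a function of distance")
  if (tether_stiffness <= 0) abort_config("tether_stiffness must be > 0")
  structure(list(construct = construct, tether_length = tether_length,
                 speed_unloaded = speed_unloaded, stall_force = stall_force,
                 off_rate_unloaded = off_rate_unloaded,
                 force_scale_detach = force_scale_detach,
                 on_rate_model = on_rate_model,
                 tether_stiffness = tether_stiffness),
            class = "motor_model")
}

#' Event-detection configuration
#'
#' A binding event is scored when the (filtered) force crosses 1 pN and stays
#' above threshold for at least 10 ms; the 10 ms dwell gate rejects sporadic
#' noise crossings.
#'
#' @param force_threshold Threshold force, pN.
#' @param min_duration Minimum time above threshold, s.
#' @param filter_points Width of the low-pass filter in samples (a 40-point
#'   filter at 3 kHz passes roughly 0-75 Hz).
#' @param filter_type `"fft"` (frequency-domain low pass) or `"boxcar"`
#'   (moving average of `filter_points` samples).
#' @param mode `"stationary"` or `"dithered"`; informational tag.
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(force_threshold = 1, min_duration = 0.010,
                             filter_points = 40,
                             filter_type = c("fft", "boxcar"),
                             mode = c("stationary", "dithered")) {
  filter_type <- match.arg(filter_type)
  mode <- match.arg(mode)
  if (force_threshold <= 0) abort_config("force_threshold must be > 0 (pN)")
  if (min_duration < 0) abort_config("min_duration must be >= 0 (s)")
  if (filter_points < 1 || filter_points != round(filter_points))
    abort_config("filter_points must be an integer >= 1")
  structure(list(force_threshold = force_threshold, min_duration = min_duration,
                 filter_points = as.integer(filter_points),
                 filter_type = filter_type, mode = mode),
            class = "detection_config")
}

#' @export
print.trap_config <- function(x, ...) {
  cat("Optical trap: k =", x$stiffness, "pN/nm, bead", x$bead_diameter,
      "nm,", x$temperature, "K,", x$sample_rate, "Hz\n")
  invisible(x)
}

#' @export
print.motor_model <- function(x, ...) {
  cat("Motor", x$construct, ": tether", x$tether_length,
      "nm, v0", x$speed_unloaded, "nm/s, stall", x$stall_force,
      "pN, koff0", x$off_rate_unloaded, "/s\n")
  invisible(x)
}
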