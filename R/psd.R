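# Thermal-calibration checks for motor-free traces: equipartition and the
# Lorentzian power spectrum of bead fluctuations in a harmonic trap.

#' Theoretical corner frequency of the trap
#'
#' `f_c = stiffness / (2 pi gamma)` with gamma the Stokes drag of the
#' configured bead; about 1.5 kHz for a 0.56 um bead at 0.045 pN/nm.
#'
#' @param trap A [trap_config()].
#' @return Corner frequency, Hz.
#' @export
corner_frequency <- function(trap) {
  gamma <- drag_coefficient(trap$bead_diameter, trap$viscosity)
  trap$stiffness / (2 * pi * gamma)
}

#' Fit a Lorentzian to the position power spectrum of a trace
#'
#' Computes the one-sided periodogram of the bead position and fits the
#' aliased Lorentzian `S(f) = sum_n D / (2 pi^2 (f_c^2 + (f + n f_s)^2))`
#' (aliases included because the corner frequency of a small trapped bead is
#' comparable to the Nyquist frequency) by least squares on the
#' log-bin-averaged spectrum.
#'
#' @param trace A motor-free `force_trace`.
#' @param n_bins Number of logarithmic frequency bins for the fit.
#' @param n_alias Number of alias terms on each side.
#' @return A list with `fc` (fitted corner frequency, Hz), `D` (fitted
#'   diffusion scale), `fc_theory` and the binned spectrum.
#' @export
fit_lorentzian_psd <- function(trace, n_bins = 60, n_alias = 5) {
  stopifnot(inherits(trace, "force_trace"))
  x <- trace$bead_position - mean(trace$bead_position)
  n <- length(x)
  fs <- trace$config$trap$sample_rate
  spec <- Mod(stats::fft(x))^2 / (n * fs)  # two-sided periodogram, nm^2/Hz
  freq <- (seq_len(n) - 1) * fs / n
  keep <- freq > 0 & freq <= fs / 2
  freq <- freq[keep]; spec <- spec[keep]

  # average into bins to stabilise the fit
  bins <- cut(freq, breaks = seq(0, fs / 2, length.out = n_bins + 1))
  fbar <- tapply(freq, bins, mean)
  sbar <- tapply(spec, bins, mean)
  ok <- is.finite(fbar) & is.finite(sbar) & sbar > 0
  fbar <- fbar[ok]; sbar <- sbar[ok]

  model <- function(f, fc, D) {
    s <- 0
    for (k in -n_alias:n_alias) s <- s + D / (2 * pi^2 * (fc^2 + (f + k * fs)^2))
    s
  }
  obj <- function(p) {
    fc <- exp(p[1]); D <- exp(p[2])
    sum((log(model(fbar, fc, D)) - log(sbar))^2)
  }
  fc0 <- corner_frequency(trace$config$trap)
  kT <- thermal_energy(trace$config$trap$temperature)
  gamma <- drag_coefficient(trace$config$trap$bead_diameter,
                            trace$config$trap$viscosity)
  D0 <- kT / gamma  # nm^2/s
  fit <- stats::optim(c(log(fc0), log(D0)), obj)
  list(fc = exp(fit$par[1]), D = exp(fit$par[2]), fc_theory = fc0,
       freq = as.numeric(fbar), spectrum = as.numeric(sbar))
}

#' Equipartition check of a motor-free trace
#'
#' Compares the sample variance of the bead position with the equilibrium
#' prediction `k_B T / stiffness` (about 91 nm^2 at 298 K and 0.045 pN/nm).
#'
#' @param trace A motor-free `force_trace`.
#' @return A list with `variance`, `expected` and their `ratio`.
#' @export
equipartition_check <- function(trace) {
  stopifnot(inherits(trace, "force_trace"))
  v <- stats::var(trace$bead_position - trace$trap_position)
  expected <- thermal_energy(trace$config$trap$temperature) /
    trace$config$trap$stiffness
  list(variance = v, expected = expected, ratio = v / expected)
}
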