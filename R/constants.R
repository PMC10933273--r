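# Physical constants and unit helpers. Internal unit system:
# length nm, force pN, time s, energy pN nm, stiffness pN/nm, drag pN s/nm.

# Boltzmann constant in pN nm / K (1.380649e-23 J/K * 1e21 pN nm / J)
.kB <- 0.01380649

#' Thermal energy k_B T
#'
#' @param temperature Absolute temperature in kelvin.
#' @return Thermal energy in pN nm (about 4.11 pN nm at 298 K).
#' @export
thermal_energy <- function(temperature) {
  if (!is.numeric(temperature) || any(temperature < 0)) {
    abort_config("temperature must be a non-negative number (kelvin)")
  }
  .kB * temperature
}

#' Stokes drag coefficient of a sphere
#'
#' @param bead_diameter Bead diameter in nm.
#' @param viscosity Dynamic viscosity in Pa s (water at 298 K is about 8.9e-4).
#' @return Drag coefficient gamma in pN s / nm.
#' @export
drag_coefficient <- function(bead_diameter, viscosity = 8.9e-4) {
  if (bead_diameter <= 0) abort_config("bead_diameter must be > 0")
  if (viscosity <= 0) abort_config("viscosity must be > 0")
  # 6 pi eta r; eta [Pa s] * r [m] gives N s/m = 1e3 pN s/nm
  6 * pi * viscosity * (bead_diameter / 2 * 1e-9) * 1e3
}

# configuration error helper: all invalid-parameter conditions share a class so
# callers (and tests) can trap them specifically
abort_config <- function(msg) {
  stop(errorCondition(msg, class = c("trapkin_config_error", "error", "condition")))
}

abort_runtime <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "trapkin_error", "error", "condition")))
}
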