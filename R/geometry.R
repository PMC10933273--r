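# Distance bookkeeping: the Snell's-law focal-shift correction applied to
# commanded stage motion, and the accessible-binding-site model relating the
# bead-microtubule gap and tether length to an on-rate.

#' Optics configuration for the axial focal-shift correction
#'
#' @param n_glass_oil Refractive index of the immersion oil / glass (1.52).
#' @param n_buffer Refractive index of the aqueous buffer (1.33).
#' @return An object of class `optics_config`.
#' @export
optics_config <- function(n_glass_oil = 1.52, n_buffer = 1.33) {
  if (!is.numeric(n_glass_oil) || n_glass_oil <= 0)
    abort_config("n_glass_oil must be > 0")
  if (!is.numeric(n_buffer) || n_buffer <= 0)
    abort_config("n_buffer must be > 0")
  if (n_glass_oil < n_buffer)
    abort_config("n_glass_oil must be >= n_buffer for a shift towards the surface")
  structure(list(n_glass_oil = n_glass_oil, n_buffer = n_buffer),
            class = "optics_config")
}

#' Snell's-law axial focal-shift fraction
#'
#' Refraction at the glass/buffer interface compresses axial stage motion:
#' moving the stage by `dz` changes the trap-bead height by only
#' `dz * (1 - shift)`. The shift fraction is
#' `(n_glass_oil - n_buffer) / n_glass_oil`, about 12% for oil (1.52) against
#' aqueous buffer (1.33).
#'
#' @param optics An [optics_config()], or the oil/glass index (with `n_buffer`
#'   as second argument).
#' @param n_buffer Buffer index when `optics` is given as a bare number.
#' @return Dimensionless shift fraction in `[0, 1)`.
#' @export
snell_shift_fraction <- function(optics = optics_config(), n_buffer = NULL) {
  if (is.numeric(optics)) optics <- optics_config(optics, n_buffer)
  if (!inherits(optics, "optics_config")) abort_config("optics must be an optics_config")
  (optics$n_glass_oil - optics$n_buffer) / optics$n_glass_oil
}

#' Correct a commanded stage increment for the focal shift
#'
#' Converts commanded axial stage motion to the effective change in the
#' bead-microtubule separation: 20 nm stage increments become 17.6 nm of
#' separation at the 12% shift, and an 80 nm range becomes 70.4 nm.
#'
#' @param stage_increment Commanded stage motion, nm.
#' @param shift_fraction Focal-shift fraction from [snell_shift_fraction()].
#' @return Effective separation change, nm.
#' @export
corrected_distance <- function(stage_increment, shift_fraction = 0.12) {
  if (!is.numeric(shift_fraction) || any(shift_fraction < 0) || any(shift_fraction >= 1))
    abort_config("shift_fraction must lie in [0, 1)")
  stage_increment * (1 - shift_fraction)
}

#' Reach geometry of a tethered motor over a microtubule lattice
#'
#' The motor is anchored at the lowest point of the bead, a height `d_B_MT`
#' above the microtubule surface; binding sites repeat every `lattice_period`
#' (8 nm, the tubulin dimer) along the filament axis within a finite window.
#'
#' @param d_B_MT Bead-surface to microtubule-surface gap, nm.
#' @param tether_length Motor + linkage contour length, nm.
#' @param bead_radius Bead radius, nm (bookkeeping only; the anchor is the
#'   bottom pole).
#' @param lattice_period Binding-site spacing along the filament, nm.
#' @param mt_length_window Half-width of the site window along the axis, nm.
#' @param lattice_offset Axial offset of the site nearest the anchor, nm.
#' @return An object of class `reach_geometry`.
#' @export
reach_geometry <- function(d_B_MT, tether_length, bead_radius = 280,
                           lattice_period = 8, mt_length_window = 200,
                           lattice_offset = 0) {
  if (d_B_MT < 0 || tether_length < 0 || bead_radius < 0 || mt_length_window < 0)
    abort_config("all lengths must be >= 0")
  if (lattice_period <= 0) abort_config("lattice_period must be > 0")
  structure(list(d_B_MT = d_B_MT, tether_length = tether_length,
                 bead_radius = bead_radius, lattice_period = lattice_period,
                 mt_length_window = mt_length_window,
                 lattice_offset = lattice_offset),
            class = "reach_geometry")
}

#' Count lattice sites reachable by the tethered motor
#'
#' A site at axial position x (height gap `d_B_MT` below the anchor) is
#' reachable when `sqrt(x^2 + d_B_MT^2) <= tether_length`. The count is zero
#' once the gap exceeds the tether length, and shrinks gradually as the gap
#' grows - the geometric picture behind the distance dependence of the
#' on-rate.
#'
#' @param geom A [reach_geometry()].
#' @return Integer number of reachable sites.
#' @export
accessible_sites <- function(geom) {
  if (!inherits(geom, "reach_geometry")) abort_config("geom must be a reach_geometry")
  if (geom$d_B_MT > geom$tether_length) return(0L)
  reach_x <- sqrt(geom$tether_length^2 - geom$d_B_MT^2)
  x <- site_positions(geom)
  sum(abs(x) <= reach_x)
}

# axial site coordinates within the window
site_positions <- function(geom) {
  w <- geom$mt_length_window
  p <- geom$lattice_period
  j <- seq.int(-floor(w / p), floor(w / p))
  x <- geom$lattice_offset + j * p
  x[abs(x) <= w]
}

#' Predicted binding rate from the accessible-site model
#'
#' On-rate proportional to the number of reachable sites:
#' `rate_per_site * accessible_sites(geom)`.
#'
#' @param geom A [reach_geometry()].
#' @param rate_per_site Binding rate per reachable site, 1/s.
#' @return Rate in 1/s.
#' @export
predicted_on_rate <- function(geom, rate_per_site) {
  if (rate_per_site < 0) abort_config("rate_per_site must be >= 0")
  rate_per_site * accessible_sites(geom)
}

#' On-rate models for the simulator
#'
#' Factories returning a function of the bead-microtubule gap d (nm) that
#' gives the binding rate (1/s). `on_rate_geometric` scales with the number of
#' reachable lattice sites; `on_rate_exponential` is an empirical
#' `rate0 * exp(-d / lambda)` decay, provided because measured binding is more
#' distance-sensitive than the site-counting model predicts;
#' `on_rate_constant` is distance-independent (zero above the reach limit is
#' still enforced by the simulator's geometry gate).
#'
#' @param rate_per_site Rate per reachable site, 1/s.
#' @param tether_length Tether length used by the geometric model, nm.
#' @param lattice_period,mt_length_window Lattice geometry, nm.
#' @param rate0 Contact (d = 0) rate, 1/s.
#' @param lambda Decay length, nm.
#' @param rate Constant rate, 1/s.
#' @return A function `f(d)` returning a rate in 1/s.
#' @name on_rate_models
NULL

#' @rdname on_rate_models
#' @export
on_rate_geometric <- function(rate_per_site = 0.1, tether_length = 60,
                              lattice_period = 8, mt_length_window = 200) {
  force(rate_per_site); force(tether_length)
  force(lattice_period); force(mt_length_window)
  function(d) {
    vapply(d, function(di) predicted_on_rate(
      reach_geometry(di, tether_length, lattice_period = lattice_period,
                     mt_length_window = mt_length_window),
      rate_per_site), numeric(1))
  }
}

#' @rdname on_rate_models
#' @export
on_rate_exponential <- function(rate0 = 1.2, lambda = 35) {
  if (rate0 < 0) abort_config("rate0 must be >= 0")
  if (lambda <= 0) abort_config("lambda must be > 0")
  force(rate0); force(lambda)
  function(d) rate0 * exp(-d / lambda)
}

#' @rdname on_rate_models
#' @export
on_rate_constant <- function(rate = 1) {
  if (rate < 0) abort_config("rate must be >= 0")
  force(rate)
  function(d) rep(rate, length(d))
}
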