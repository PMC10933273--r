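---
title: "Models and methods behind trapkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind trapkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`trapkin` is a simulation and analysis pipeline for measuring the *onset*
of single-molecule protein–protein interactions in an optical-trap bead
assay: a motor protein on a trapped bead, held at a controlled gap
`d_B-MT` above a microtubule, binds, walks, and detaches; the force trace
read from the position detector is scored into binding events, and the
intervals between a detachment and the next binding give the rebinding
rate — an on-rate proxy — as a function of distance and tether length.
This vignette describes the models, the parameters that matter, the
numerical choices, and what the synthetic data can and cannot establish.

## Bead and trap model

The bead is overdamped, so its position $x$ along the filament axis obeys

$$\gamma\,\dot x = -k_\mathrm{trap}\,(x - x_\mathrm{trap}(t)) + F_\mathrm{tether} + \sqrt{2 k_B T \gamma}\,\xi(t),$$

with $\gamma = 6\pi\eta r$ the Stokes drag (4.7 × 10⁻⁶ pN s/nm for a
0.56 µm bead in water at 298 K) and the noise amplitude fixed by the
fluctuation–dissipation relation. Two consequences are used as built-in
sanity checks on every motor-free trace:

* equipartition, $\mathrm{var}(x) = k_B T / k_\mathrm{trap}$ (≈ 91 nm² at
  the default 0.045 pN/nm), via `equipartition_check()`;
* a Lorentzian position spectrum with corner frequency
  $f_c = k_\mathrm{trap}/(2\pi\gamma)$ (≈ 1.5 kHz), via
  `fit_lorentzian_psd()`. Because $f_c$ is comparable to the 1.5 kHz
  Nyquist frequency of the 3 kHz force channel, the fit uses the *aliased*
  Lorentzian (alias terms summed over ±5 sampling frequencies) on a
  log-binned periodogram; a naive Lorentzian fit would be biased high.

The force channel is $F = k_\mathrm{trap}(x - x_\mathrm{trap})$, i.e. what
a back-focal-plane position detector calibrated in force units reports.

### Integration scheme

The output grid is 1/3000 s, but the bead relaxation time
$\gamma/k_\mathrm{trap}$ is only ~0.1 ms, so the equation is integrated on
an internal substep no larger than one tenth of the relevant relaxation
time and then decimated (not averaged — averaging would distort the
spectrum) onto the output grid. Two regimes are treated differently:

* **Unbound.** The trap-only dynamics are an Ornstein–Uhlenbeck process,
  which is propagated with the *exact* exponential update
  ($x \mapsto x_t + (x - x_t)e^{-\Delta t/\tau}$ plus a Gaussian of
  variance $\frac{k_BT}{k}(1 - e^{-2\Delta t/\tau})$), the trap position
  frozen within a substep. A plain Euler–Maruyama step of size
  $0.1\,\tau$ inflates the stationary variance by exactly
  $1/(1 - \Delta t/2\tau) \approx 5\%$ — right at the edge of the
  equipartition check — which is why the exact update is used.
* **Bound.** The tether force is piecewise linear (see below), so no exact
  update exists; Euler–Maruyama is used with the substep tied to the
  *combined* stiffness, $\Delta t \le 0.1\,\gamma/(k_\mathrm{trap} +
  k_\mathrm{tether})$.

A user-supplied `internal_dt` coarser than the unbound bound raises an
explicit stability error rather than integrating inaccurately. All
randomness flows through R's RNG (the compiled core uses `norm_rand()` /
`unif_rand()`), so a trace is a deterministic function of its configuration
and seed.

## Motor model

The motor is intentionally minimal — the analysis never resolves single
steps at 3 kHz, so stepping is continuous:

| parameter | default | units | rationale |
|---|---|---|---|
| `tether_length` | 35 / 60 / 85 | nm | DK406 / K560 / DK746 presets: ~0.15 nm of coiled-coil rise per residue beyond the ~370-aa motor domain, plus ~30 nm of antibody–streptavidin linkage; K560 matches the ~60 nm combined linkage of the assay |
| `speed_unloaded` | 800 | nm/s | kinesin-1 at saturating ATP |
| `stall_force` | 6 | pN | linear force–velocity to stall |
| `off_rate_unloaded` | 1 | 1/s | order of kinesin's unloaded detachment; free parameter |
| `force_scale_detach` | 2 | pN | Bell detachment scale; the dither-enhanced off-rate is not quantified experimentally, so this is exposed rather than asserted |
| `tether_stiffness` | 0.2 | pN/nm | tether is slack (zero force) below its rest length, a stiff spring beyond it |

Binding is a Poisson process at rate `on_rate_model(d_B_MT)`, gated by
geometry: if no lattice site is within tether reach the rate is zero
regardless of the model. On binding the motor anchors at the lattice site
(8 nm period) nearest the bead's current position; while bound it walks in
the plus direction at $v = v_0\,(1 - F_h/F_\mathrm{stall})^+$, where $F_h$
is the hindering tension, and detaches at
$k_\mathrm{off}\exp(|F|/F_d)$.

The tether connects the anchor site to the bead along the filament axis;
the vertical gap is folded in by projecting the rest length,
$L_x = \sqrt{L^2 - d_{B\text{-}MT}^2}$, a one-dimensional simplification.
With the defaults, a motor binding near the trap centre must travel
roughly $L_x + F_\mathrm{thr}/k_\mathrm{tether} + F_\mathrm{thr}/k_\mathrm{trap}
\approx 105$ nm before the force reaches the 1 pN detection threshold —
reproducing the order of magnitude (~120 nm, ~0.1 s at 800 nm/s) that
motivates dithering the trap.

## Distance bookkeeping and on-rate models

Commanded axial stage motion is compressed by refraction at the
glass/buffer interface: `snell_shift_fraction()` returns
$(n_\mathrm{oil} - n_\mathrm{buffer})/n_\mathrm{oil} = 0.125$ for
1.52/1.33, and `corrected_distance()` applies the assay's rounded 12%
(20 nm → 17.6 nm, 80 nm → 70.4 nm).

Two distance→rate models are provided. `on_rate_geometric()` counts the
8 nm lattice sites whose distance from the bead's bottom-pole anchor is
within tether reach (`accessible_sites()`, window ±200 nm so counts are
never truncated for any preset tether) and multiplies by a per-site rate.
This predicts a *gradual* decline with distance; measured binding falls
off more steeply, so the default for demonstrations is the empirical
`on_rate_exponential(rate0 = 1.2, lambda = 35)` — a contact rate of
1.2 s⁻¹ (the measured scale of single-kinesin rebinding) decaying over
35 nm, which spans a factor > 4 across a 50 nm sweep, the dynamic range
the distance dependence shows experimentally. The anchor is the bead's
nearest point to the filament; averaging over anchor positions on the
bead cap, cylindrical microtubule geometry, and vertical bead
fluctuations extending the reach are deliberately out of scope.

## Event detection

The scoring criteria are: low-pass filter, then a 1 pN threshold on the
absolute force with a ≥ 10 ms dwell gate (filter-then-threshold; both
orders are testable by calling `smooth_trace()` explicitly). The
"40-point" filter is interpreted as a frequency-domain low pass with
cutoff `sample_rate/40` (75 Hz at 3 kHz); a 40-sample moving average is
available as `filter_type = "boxcar"`. The FFT path reflection-pads the
series (and extends the pad to the next 5-smooth length, since R's
mixed-radix FFT degrades badly on lengths with large prime factors).
Detachment is the downward re-crossing of the threshold after filtering;
events touching the trace boundary are flagged `truncated` and excluded
from bound-time and peak-force statistics. Raising the threshold can
*split* one long excursion into several events (each nested in the
original), so event counts are not monotone in the threshold; they are
monotone in the dwell gate.

In dithered mode the commanded triangular waveform is known, so the
expected free-bead force — the deterministic drag-model response,
integrated from the waveform alone so that binding can never contaminate
the reference — is subtracted, and the residual is filtered and
thresholded with the same criteria. A bound tether is stretched once or
twice per dither period, producing recurring threshold crossings;
crossings separated by less than one period are merged into a single
event (one tether, one event). On noiseless traces every event lasting at
least `1/f` is detected, with latency below one period plus one filter
window; at the default noise the residual threshold sits ~10σ above the
filtered Brownian noise, so false positives are negligible.

## Kinetics and statistics

Rebinding time is the gap from a detachment to the next event start;
`rebinding_times()` refuses overlapping events, the rate is the
reciprocal mean, and `rate_from_mean_time()`/`time_from_rate()` are exact
reciprocals. Intervals never span a trace boundary (discarded, not
censoring-corrected — the assay does not describe censoring either).
Empty cells yield `NA` statistics, never zero. Because detected event
starts lag true bindings (by up to a dither period) and detected ends can
precede true unbindings, detection-based mean intervals carry a small
positive bias — a few percent at rates around 1 s⁻¹ with 20 Hz dithering —
which is a property of the measurement itself, shared with the
instrument pipeline; recovery tests therefore compare at the 10% level.

## Focus lock and surface finding

Bead images are a Gaussian-spot proxy for a defocused bead on a 40×40
grid: blur radius grows in quadrature with defocus over a 300 nm scale,
total intensity conserved (blur redistributes light). The match score is
the zero-normalised cross-correlation × 1000 (1000 = perfect match,
symmetric, undefined — an explicit error — on constant images). The
proprietary instrument metric is not reproduced; the cross-correlation
satisfies every property the method relies on: a quadratic peak at the
template's defocus and steep, nearly linear flanks near the surface,
which is why the operating template is rendered 300 nm out of focus.

The controller is purely proportional with unity loop gain through the
calibrated slope (score change per nm over a commanded 100 nm excursion;
calibration fails explicitly when the excursion straddles the score
vertex, where the slope vanishes). Images arrive at 25 Hz and corrections
are applied every 1 s, both configurable; a sampled proportional loop
bounds the residual error under ramp drift at
`drift_rate × correction_interval` plus the noise floor.

Surface finding steps the stage upward in 10 nm increments, averaging 25
score frames per step. The trapped bead stays in the focal plane — its
score is flat — until the surface displaces it; contact is declared at the
first step whose mean score departs from the running baseline by a
noise-scaled threshold (5σ of the per-step mean by default), and the
contact height is then refined by dividing the trigger step's score
excess by the post-contact slope estimated from three further steps.
Noiseless input recovers the contact height exactly; with noise the error
stays within one approach step. Starting already in contact triggers at
the first step and reports the scan origin.

## What the generator does and does not emulate

The simulator reproduces the features the pipeline's logic depends on:
thermal bead statistics with the correct spectrum, distance-gated Poisson
(re)binding, load-dependent walking and detachment, the slack-tether
detection latency, triangular dithering, slow stage drift, and
defocus-dependent template scores. It does **not** emulate discrete 8 nm
stepping, vertical (z) bead fluctuations or trap anisotropy, multiple
motors per bead (excluded in the assay too), photodamage, instrument
drift of the force detector, or the true far-from-focus shape of the
score curve. Passing tests therefore validate the *computations* —
scoring, statistics, corrections, control — under a faithful physical
stand-in, not the instrument hardware, and say nothing about, e.g., how
real score curves behave hundreds of nm from focus.

## Problem sizes and seeds in the shipped tests

The suite is sized for a single CPU: oracle-equivalence runs use 1000
short random force series; the detection-floor check uses ~100 scripted
noiseless events; equipartition and spectral checks use one 60 s
motor-free trace; recovery uses five distances × ~500 events per cell
(four repeats each); surface finding uses 100 randomized contact heights.
All seeds are fixed constants in the tests; the acceptance script takes
its seed on the command line.
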