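# trapkin

Tools for quantifying how single-molecule protein–protein interactions
*begin*: the on-rate of a motor protein (re)binding its filament, measured in
an optical-trap bead assay as a function of the distance between the two
partners and of the motor's tether length.

Most single-molecule trap work characterises a bond *after* it has formed
(unbinding under load). Measuring the *initiation* of binding instead
requires (i) nanometre-stable control of the gap `d_B-MT` between the
trapped bead's surface and the microtubule, held by a template-match focus
lock on a fiduciary bead, and (ii) a detection scheme that scores binding
events from the force trace quickly enough that short events are not lost.
`trapkin` implements that measurement pipeline end to end, with a stochastic
simulator standing in for the instrument so that every stage can be
validated against ground truth.

## What is inside

* **Simulator** (`simulate_trace()`, `generate_sweep()`): overdamped Langevin
  dynamics of a 0.56 µm bead in a harmonic trap (k ≈ 0.045 pN/nm, force
  sampled at 3 kHz), with a single motor that binds at a distance-dependent
  Poisson rate, walks with a linear force–velocity relation (default
  800 nm/s unloaded, 6 pN stall), pulls the bead through a slack-then-stiff
  tether, and detaches at a Bell rate `k_off exp(|F|/F_d)`. Ground-truth
  bind/unbind times are recorded for every event. The trap can be dithered
  as a triangular wave (10/20 Hz, 200 nm peak to peak) along the filament
  axis.
* **Event detection** (`detect_events()`, `detect_events_dithered()`): the
  assay's scoring criteria — low-pass filter over a 40-sample scale, a
  1 pN force threshold and a ≥ 10 ms dwell gate. In dithered mode the
  expected free-bead response to the commanded waveform is subtracted and
  the residual is scored, which detects every tether that survives one
  dither period (`1/f` s).
* **Kinetics** (`rebinding_times()`, `summarize_sweep()`,
  `histogram_summaries()`): rebinding time = interval from a detachment to
  the next binding; its reciprocal mean is the rebinding rate, resolved by
  `d_B-MT` and motor construct (DK406 / K560 / DK746 tether presets).
* **Geometry** (`snell_shift_fraction()`, `corrected_distance()`,
  `accessible_sites()`): the Snell's-law focal-shift correction — commanded
  axial stage motion is compressed by `(n_oil − n_buffer)/n_oil` ≈ 12%, so
  20 nm commanded steps are 17.6 nm of true separation — and a geometric
  model counting the 8 nm-spaced lattice sites within tether reach, one of
  the selectable on-rate models.
* **Focus lock** (`render_bead_image()`, `match_score()`,
  `calibrate_slope()`, `run_focus_lock()`, `find_surface()`): 40×40
  defocused-bead templates, the 0–1000 normalised cross-correlation score,
  slope calibration from a 100 nm excursion, a proportional 1 s correction
  loop, and surface identification from the trapped-bead score during a
  10 nm-step approach.
* **Orchestration** (`validate_config()`, `run_pipeline()`): YAML
  configuration with assay defaults, and a seeded simulate → detect →
  summarise run that writes traces, event tables, summaries and a
  checksummed manifest.

## Worked example

Simulate four minutes of a K560 bead held 20 nm above a microtubule, once
with a stationary and once with a dithered trap, and compare what the two
detection modes recover:

```r
library(trapkin)
trap  <- trap_config()                      # 0.045 pN/nm, 0.56 um bead, 3 kHz
motor <- motor_model("K560", on_rate_model = on_rate_exponential(1.2, 35))

still <- simulate_trace(trap, dither_config(), motor,
                        d_B_MT = 20, duration = 240, seed = 1)
dith  <- simulate_trace(trap, dither_config(TRUE, 20, 200), motor,
                        d_B_MT = 20, duration = 240, seed = 1)

ev_st <- detect_events(still)               # 1 pN / 10 ms criteria
ev_di <- detect_events_dithered(dith)       # dither-aware residual detection
m_st <- evaluate_detection(ev_st, still$true_events)
m_di <- evaluate_detection(ev_di, dith$true_events)
```

which prints

```
stationary trap: 114/136 true events detected, mean latency 0.109 s
dithered trap:   127/134 true events detected, mean latency 0.010 s
event_statistics: 135 events; mean rebinding time 1.6 s (rate 0.626 /s);
  mean bound time 0.183 s; mean peak force 5.35 pN
detected event rate: 28.50/min stationary vs 33.75/min dithered (+18%)
```

The stationary trap only sees an event once the motor has walked far enough
(~100 nm of travel) to build 1 pN of force, hence the ~0.11 s latency; the
dithered trap stretches a freshly formed tether within one 50 ms sweep, so
events are found ~0.1 s sooner and short events that the stationary
criteria miss are recovered — more detected events and a correspondingly
higher apparent rebinding rate, the qualitative signature the method is
built around.

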