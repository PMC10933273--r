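Package: trapkin
Title: Optical-Trap Simulation and Kinetics of Single-Motor Binding Events
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the initiation of single-molecule
    protein-protein interactions with an optical trap. Provides a stochastic
    (overdamped Langevin) simulator of a trapped bead carrying a tethered
    processive motor near a microtubule, with distance-dependent binding,
    load-dependent stepping and Bell-type detachment; force-trace binding-event
    detection with threshold and dwell criteria in both stationary-trap and
    dithered-trap modes; rebinding-time and rebinding-rate statistics resolved
    by bead-microtubule separation and motor tether length; a Snell's-law
    focal-shift correction and a geometric accessible-binding-site model; and a
    simulated template-match focus lock with drift correction and surface
    finding.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
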