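Package: sonojet
Title: Microbubble Dynamics, Kelvin Impulse and Stress Analysis for
    Sonoporation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for ultrasound-driven
    lipid-coated microbubbles interacting with a cell layer on a rigid
    substrate. Solves coated-bubble radial dynamics (Keller-Miksis
    compressible liquid, Marmottant shell, pluggable reduced gas model),
    couples them to the translational force balance of a bubble pressing
    into a fractional-viscoelastic (spring-pot) cell layer via the
    L1-discretized Caputo derivative, decomposes the per-cycle Kelvin
    impulse into ultrasound and substrate contributions with the
    associated jet anisotropy parameter, compares the stress mechanisms a
    bubble exerts on a cell (water-hammer, stagnation, impact, shear,
    streaming, Bjerknes cross-section pressures), classifies jetting and
    sonoporation events against radial-expansion thresholds, and fits the
    Hertz contact model to AFM force-indentation curves. Includes
    synthetic-data generators emulating high-speed-camera radius tracks,
    hydrophone pulse envelopes, jetting-event sweeps and noisy Hertzian
    force curves so every stage is testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
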