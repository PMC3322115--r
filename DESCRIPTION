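Package: v1column
Title: Feedforward Rate Model of a Primary Visual Cortex Column
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Mechanistic simulation of a single column of cat primary visual
    cortex built from on- and off-centre X-cell pathways. Sub-cortical
    channels pool local contrast with difference-of-Gaussians receptive
    fields and cascaded first-order low-pass filters; three rectifying
    cortical stages convert the geniculate drive into simple- and
    complex-like responses. Includes the stimulus battery (drifting and
    contrast-reversing gratings, spots, bars), an adaptive Runge-Kutta
    simulation engine with an analytic linear-regime oracle, and in-silico
    experiments: receptive-field maps, orientation and spatial-frequency
    tuning, direction selectivity, spatiotemporal receptive fields,
    phase-advance scans, modulation ratios, and multi-column population
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
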