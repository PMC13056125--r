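Package: spheromech
Title: Force-Direction-Dependent Integrin Activation and Platelet Mechanics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for motion-dependent platelet activation in
    blood-contacting devices. Extracts rupture events and pre-rupture
    unfolding peaks from atomic force microscopy force-displacement curves
    with a 1.96-SD significance rule; computes the Forster resonance energy
    transfer photophysics chain (spectral overlap integral, Forster radius,
    efficiency/distance inversion, two-state mixture estimates of the
    activated integrin fraction); provides a coarse-grained bond-graph model
    of anisotropic integrin alphaIIb-beta3 unfolding under tangential versus
    normal loading; classifies platelet wall motion as rolling or sliding
    from centroid and orientation tracks; and summarises extracorporeal
    circuit coagulation metrics (pressure-rise clotting time, occlusion
    ratio, activated clotting time, dose conversion). Includes seeded
    synthetic-data generators for every input so the whole chain is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
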