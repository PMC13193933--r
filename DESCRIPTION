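Package: rfdinterfere
Title: Predicting Interference of Acute Aerobic Exercise on Rate of Force Development
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Implements a nonlinear exponential-decay dose-response model for the
    acute interference of aerobic exercise on the rate of force development (RFD)
    measured from an isometric mid-thigh pull. Provides single-point and tabular
    prediction of post-exercise RFD, absolute and percent loss, a linear comparison
    variant, parameter sensitivity sweeps over the decay rate and scaling factor,
    simulation of post-exercise force-time curves with slope-based RFD recovery,
    packaged athlete baseline profiles, and a coach-facing command-line interface
    with CSV/JSON export and config-file support.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
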