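Package: needleEIS
Title: Bioimpedance Tissue Identification for Needle-Insertion Guidance
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for identifying soft-tissue layers from multi-frequency
    electrical impedance spectra during simulated needle insertion. Provides
    saline-calibrated remapping of impedance magnitude to conductivity,
    a variational Bayesian neural-network classifier with posterior-sampling
    confidence estimates, a synthetic layered-tissue phantom generator, a
    closed-loop stop-at-target insertion simulator with
    comfortable-travel-distance (overshoot) metrics, and CSV/JSON interchange
    formats plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
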