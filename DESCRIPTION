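Package: oph
Title: Ratiometric Optical pH Sensing of Dental Biofilm
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis toolkit for ratiometric fluorescein-based
    optical pH measurement of dental biofilm. Provides a forward model of
    pH-dependent two-species fluorescein emission acquired through four
    filtered, lock-in demodulated photodetector channels; FFT amplitude
    extraction at the LED modulation frequency; linear ratio-to-pH
    calibration with autofluorescence and signal-level quality gating;
    replicate aggregation and pooled-standard-deviation repeatability;
    clinical group comparisons (Welch and permutation tests) over a seeded
    synthetic cohort generator emulating a rest/drop sugar-rinse protocol;
    and per-pixel pH imaging with validity masking for two-channel frame
    stacks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    optparse,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
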