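Package: tfbcsp
Title: Temporal-Spectral Filter-Bank Common Spatial Patterns for
    Motor-Imagery EEG Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Decodes two-class motor imagery from epoched multichannel EEG
    using a temporal-spectral filter bank of Common Spatial Patterns (CSP)
    features, exhaustive Sequential Backward Selection over the
    band-by-window feature grid, and an exact-design radial basis function
    network classifier. Includes Butterworth preprocessing, confusion-matrix
    metrics with Cohen's kappa, nested cross-validation drivers with
    parameter sweeps and ablation grids, a plain-text epoch container, and a
    seeded synthetic EEG generator with planted class-discriminative band
    power for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
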