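Package: rhizocount
Title: Automated Counting of Broomrape Tubercles on Rhizotron Root Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Calibrated colour-threshold phenotyping of sunflower broomrape
    (Orobanche cumana) infestation from rhizotron images. Implements the full
    measurement chain used in high-throughput tubercle counting: millimetre
    scale calibration, region-of-interest cropping, HSB (hue/saturation/
    brightness) colour thresholding, binary-mask hole filling, and
    connected-component particle analysis with an area filter, plus batch
    directory processing with summary tables, a manual add/delete correction
    workflow, object-level detection matching and count-agreement statistics
    (Pearson correlation and trend line through the origin), and a seeded
    synthetic rhizotron-image generator with exact ground truth for
    benchmarking the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    stats,
    utils,
    tools,
    png,
    tiff,
    jpeg,
    yaml,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
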