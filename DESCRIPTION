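Package: wiltflow
Title: Optical-Flow Leaf Wilting and Stem-Diameter Lag Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies short-term leaf wilting of greenhouse plants from
    time-lapse RGB images using dense optical flow, excess-green (ExG)
    vegetation masking and a two-bin histogram of oriented optical flow, and
    relates it to short-term stem-diameter variation via per-day lagged
    cross-correlation. Includes the relative stem diameter (RSR) irrigation
    controller used to impose cyclic water stress, regression of the per-day
    correlation peak against daily mean light (PPFD) and vapor-pressure
    deficit (VPD), and a synthetic greenhouse simulator (soil-stem-leaf
    reservoir chain with a configurable water-transport delay, plus a frame
    renderer) so the whole pipeline can be exercised end to end with a known
    ground-truth lag.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
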