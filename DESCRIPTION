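Package: beatkit
Title: Quantification of Beating-Heart Time-Lapse Microscopy
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying cardiac time-lapse microscopy of the
    embryonic zebrafish heart: kymograph-based classification of blood flow
    through the atrioventricular canal into anterograde, retrograde and
    no-flow fractions per beating cycle; heart-wall midline segmentation with
    per-segment diameter and fluorescence profiles; retrospective phase
    alignment and 4D assembly of plane-by-plane calcium imaging movies; valve
    leaflet morphometry and deduplicated cell counting; and the accompanying
    statistics (two-sided Fisher exact test, Student's t-test, 2^-ddCt qPCR
    fold changes). Includes a seeded synthetic beating-heart movie generator
    that provides ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
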