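Package: flashhazard
Title: Photosensitive-Epilepsy Flash-Hazard Analysis of Video Content
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects potentially seizure-inducing flashing in video frame
    sequences. Implements a harmonized flash-hazard provision (luminance and
    saturated-red transitions, 66 ms qualifying duration, 20 ms synchronicity
    window, fast-flash merging, 10-degree-field area thresholds) together with
    selectable conformance profiles for the five major international
    guidelines (WCAG 2.x, ISO 9241-391, ITU-R BT.1702, Ofcom, NHK/JBA).
    Includes full colorimetry (sRGB, BT.1886, PQ and HLG transfer functions,
    CIE 1976 UCS chromaticity), viewing-geometry conversions, and a synthetic
    test-pattern generator with analytically known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
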