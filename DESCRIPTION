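Package: armswing
Title: Arm Swing Quantification from Wrist-Worn Gyroscopes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies arm swing during walking from the raw 3-axis angular
    velocity of a wrist- or forearm-worn gyroscope. A zero-phase low-pass
    filter, a principal-component projection of the two transverse axes onto
    the swing direction, trapezoidal integration and a symmetric
    moving-average detrend yield the swing angle; sliding-window spectral
    gating, prominence-based extrema detection and a cascade of retention
    filters yield per-swing events. Per-arm summaries (amplitude, peak
    angular velocity, percent swing time, frequency, regularity) and
    bilateral summaries (simultaneity, asymmetry index, coordination) follow,
    together with a synthetic bilateral signal generator with exact ground
    truth and Bland-Altman style agreement statistics for validating the
    pipeline against that truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
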