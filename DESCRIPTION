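Package: collartrack
Title: Fiducial Collar-Tag Tracking of Animal Resource Use
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for monitoring resource use by collar-wearing animals with
    printed square fiducial markers. Generates marker dictionaries with
    rotation-invariant Hamming-distance guarantees and printable collar
    strips, detects and decodes markers in video frames, attributes
    detections to regions of interest around resources (food and water
    bowls), logs spatio-temporal events in post-event or real-time mode,
    segments behaviour bouts from presence series, and validates tracker
    output against human-coded ethogram data with intraclass correlation
    coefficients and Cohen's kappa. Includes a seeded synthetic-scene
    generator producing ground-truth frames and simulated human codings so
    the whole pipeline is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
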