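Package: shearwatR
Title: Behaviour Detection from Accelerometry for Shallow-Diving Seabirds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects flight, take-off, surface seizing, foraging dives and
    rest in shallow-diving seabirds from tri-axial body acceleration alone.
    Per-tag thresholds are calibrated from spectrally estimated flight
    minutes (flap-band versus take-off-band spectrogram energy), flapping is
    isolated by the trough of a bimodal kernel density of dorsoventral
    acceleration peak-trough differences, foraging is detected from large
    pitch excursions, and rest from a moving average of overall dynamic body
    acceleration. Includes duration-based validation against a reference
    ethogram (true/false positive rates), integration of detections with GPS
    tracks (speed filters, trip segmentation, daily activity budgets), and a
    seeded synthetic labelled-signal generator so the full pipeline can be
    exercised without field data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    geosphere,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
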