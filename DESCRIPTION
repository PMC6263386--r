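Package: harvestmap
Title: Greenhouse Harvesting Maps from Beacon RSSI and Wrist-Worn IMU Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Automatic recording of greenhouse harvesting work from wearable
    sensors. Estimates a laborer's section-level position from Bluetooth
    beacon RSSI logs (two-strongest-beacon interpolation, mode filtering and
    passage-constrained map matching), detects individual ~1 s harvesting
    actions from 50 Hz wrist acceleration (SAX and gradient window histogram
    features scored by a random forest, with rule-based event extraction),
    and fuses the two streams into a per-section harvesting map of yield
    counts. Includes a synthetic-data generator that emulates a
    passage-constrained walk, log-distance RSSI propagation and stereotyped
    harvesting-action bursts, so the whole pipeline can be exercised and
    evaluated without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    randomForest,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
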