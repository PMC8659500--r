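Package: cowcollar
Title: Calving Detection from Neck-Collar Accelerometer Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for working with binary sensor logs from neck-mounted
    cattle collars and for predicting the onset of calving from them.
    Includes a bit-exact reader/writer for the fixed-width collar record
    format, synchronisation of observer behaviour annotations with sensor
    streams, threshold-based standing/lying posture classification from
    Y-axis accelerometer readings, a rolling lying-bout statistic that
    rises before parturition, per-animal alarm calibration with gestation
    gating, and a behaviour simulator that generates collar streams and
    annotations with realistic bout dynamics for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
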