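Package: bovact
Title: Lying Behavior and Activity of Cows from Leg-Worn Triaxial Accelerometers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyze the lying behavior of cows from raw triaxial accelerometer
    data recorded on a hind leg. Provides a pipeable, data-frame-first workflow:
    import and axis mapping of raw logger files, gravity-component extraction by
    moving-median or zero-phase Butterworth low-pass filtering, rule-based
    classification of lying versus standing posture with minimum-bout-duration
    correction, assignment of lying laterality (left/right side), per-sample
    proxies for physical activity (L1/L2 norms of dynamic body acceleration and
    of jerk), bout-wise and interval-wise summaries with fractional-overlap
    weighting, and extraction of posture-transition windows. Includes a
    synthetic-data simulator with per-sample ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    lubridate,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
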