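Package: timask
Title: Time-Intensity Sensory Curve Analysis and Flavor-Masking Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for time-intensity (TI) sensory evaluation of flavoring
    materials: smoothing and averaging of panelist TI curves, extraction of
    the 14 standard TI parameters (onset, peak, plateau bounds, phase
    durations, maximum phase slopes and phase areas), visual-analog-scale
    (VAS) based flavor-masking scores, correlation-based parameter pruning,
    exact Mann-Whitney U comparison of top and bottom masking groups, and
    PCA plus seeded k-means classification of materials by their TI
    profiles. Includes a fully seeded synthetic sensory-panel generator
    with closed-form parameter oracles so the complete pipeline runs and
    is testable without proprietary panel data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
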