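Package: pedtrack
Title: Pedestrian GPS Trajectory Cleaning, Geomasking and Movement Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for processing purpose-based pedestrian GPS trajectories
    (home-to-school commutes and similar origin-destination trips): reading and
    writing the raw and processed track CSV dialects, kinematic featurization
    on the time-advanced convention (step intervals, distances, instantaneous
    velocities), a five-stage filtering and cleaning pipeline (non-pedestrian
    removal, origin-destination validation, outlier clean-up, spatial
    k-anonymity geomasking with a housing-density disclosure-risk model, and
    1 Hz linear interpolation), and the movement statistics used for technical
    validation (velocity distributions, mean squared displacement, and the
    autocorrelation of log-normalized velocities). A seeded synthetic cohort
    generator with a ground-truth ledger makes every stage testable without
    access to the original field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    broom,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    geosphere,
    graphics,
    stats,
    tidyselect,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
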