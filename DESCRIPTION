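Package: vesselbird
Title: Seabird-Fishing Vessel Encounter and Attendance Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs fishing-vessel trajectories from vessel monitoring
    system (VMS) records and fishing-operation logs, joins them to seabird GPS
    tracks, segments bird-vessel encounter events and attendance behaviour
    under configurable distance and speed thresholds, builds vessel-activity
    covariates, and fits mixed-model regressions for encounter rate,
    attendance probability, attendance duration, proportion and distance, plus
    a mass-gain linear model. Includes a synthetic-data generator emulating
    central-place foraging trips and a small longline fleet with night
    setting and daytime hauling, and a threshold sensitivity sweep.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    glmmTMB,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
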