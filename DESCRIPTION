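Package: penfeedr
Title: Meal-Based Feeding Behaviour, Social Ranking and Feed Efficiency
    Phenotypes from Electronic Feeder Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns raw electronic-feeder visit logs from group-housed
    growing-finishing pigs into meal-based feeding-behaviour traits,
    feeder-access social-ranking indicators, and growth and feed-efficiency
    phenotypes. Visits are merged into meals using per-animal meal criteria
    estimated from the discrete hazard of starting a new visit (Pstart) with
    rolling smoothing; anomalous meals are removed by robust Mahalanobis
    distances from Minimum Covariance Determinant estimates; residual feed
    intake and residual gain are derived from within-breed regressions; and
    per-animal trait averages are correlated with significance flags. A
    synthetic pen simulator with bimodal circadian feeding intensity,
    two-timescale inter-visit gaps, single-feeder occupancy queuing and
    dominance-linked access generates realistic logs plus latent truth, so
    the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lubridate,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
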