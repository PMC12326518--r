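Package: aascall
Title: Spatiotemporal Analysis of Fish Aggregation-Associated Sound Detections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing aggregation-associated sound (AAS) detections
    recorded by a hydrophone array at a fish spawning aggregation. Provides a
    seeded synthetic-data generator (array geometry, fish-mass trajectories,
    Poisson-lognormal hourly counts, per-minute detection streams with vessel
    interference, paired classifier label streams), detection preprocessing
    (2-s dedup binning, interference subsampling and window exclusion, effort
    computation, hourly aggregation, abundance and proximity categorisation),
    confusion-matrix evaluation of automatic call classifiers including
    Cohen's kappa and pooled metrics, a Bayesian hierarchical Poisson
    call-rate model with an effort offset and hour-level multivariate-normal
    station random effects under an LKJ correlation prior (fit by a built-in
    Hamiltonian Monte Carlo sampler with split R-hat and effective-sample-size
    diagnostics), and a spatial analysis of posterior inter-station
    correlations against great-circle distance with a correlation-distance
    regression and its zero crossing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    broom,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
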