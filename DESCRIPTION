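Package: grwtrend
Title: Directional Random Walks, Generalized Least Squares and Peak
    Tracking for Sparse Fossil Time Series
Version: 0.1.0
Authors@R:
    person("grwtrend", "maintainers", email = "grwtrend@example.org",
           role = c("aut", "cre"))
Description: Tools for inferring directional evolution from sparse,
    noisy fossil time series of mean trait values.  Simulates general
    random walk (GRW) trait evolution with realistic sampling error,
    fits the GRW model by maximum likelihood over ancestor-descendant
    transitions (allowing and flagging negative step-variance
    estimates, which are clamped to zero), fits linear trends by
    generalized and weighted least squares with a random-walk
    covariance structure, and compares methods by weighted mean squared
    prediction error in seeded Monte-Carlo studies.  Also provides an
    adaptive-peak-tracking stage that regresses trait means on a
    smoothed environmental proxy, with log-transform error propagation,
    plus a command-line interface for simulation, fitting, study
    replication and case analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
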