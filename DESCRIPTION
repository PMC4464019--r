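Package: EnsembleKinetics
Title: Ensemble Statistics and Reports for Stochastic Kinetic Time Series
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Turns ensembles of stochastic simulation trajectories (one
    delimited text file per run) into statistical reports: ensemble mean and
    standard deviation traces, per-time probability densities with Gaussian
    maximum-likelihood fits, empirical master-equation estimates over time
    intervals, and 2D/3D phase spaces. Ships a Gillespie direct-method
    simulator with built-in reaction models (Lotka-Volterra predator-prey,
    immigration-death, pure death) for generating validated fixture datasets,
    SBRML time-course import and export, a content-addressed result cache,
    plotting of every statistic, and a batch report runner with a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    parallel,
    data.table,
    Rcpp,
    rlang,
    xml2,
    yaml,
    jsonlite,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
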