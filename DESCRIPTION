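Package: haltloss
Title: First-Derivative Tests for Halt-the-Loss Biodiversity Targets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess "halt-the-loss" biodiversity targets with a
    probabilistic first-derivative test. A multi-species abundance indicator is
    fitted as a Bayesian state-space model in which species' log abundance
    trajectories share a spline-smoothed common growth rate; the test reports,
    for each year, the posterior probability that this growth rate is at or
    above zero. The package also provides the simulation machinery needed to
    calibrate the test case-by-case: generation of species time series with
    controlled interspecific, interannual and measurement-error variability,
    appending of simulated futures to historical data, species-level
    pre-smoothing with thin-plate regression splines, replicated scenario
    experiments with averaged probabilities and outcome histograms, and
    false-positive/false-negative error-rate tables for threshold selection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    rjags,
    coda,
    mgcv,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
SystemRequirements: JAGS (>= 4.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
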