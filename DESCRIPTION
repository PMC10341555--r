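Package: tugfall
Title: Sensor-Based Fall-Risk Feature Analysis for Timed-Up-and-Go Trials
Version: 0.1.0
Authors@R:
    person("tugfall", "maintainers", email = "tugfall@example.org",
           role = c("aut", "cre"))
Description: Extracts a 79-feature catalogue (multiscale sample entropy,
    permutation entropy, transition, gait and turning descriptors) from
    waist-worn triaxial accelerometer recordings of Timed-Up-and-Go (TUG)
    trials, ranks the features with a from-scratch Relief-F implementation
    and impurity-based tree-ensemble importances, classifies subjects under
    three clinical fall-risk labelings (TUG duration, short-form Berg
    balance scale, and their union) with resampled random forests, and
    intersects the feature sets of the best models. Ships a synthetic
    two-cohort TUG signal generator so the whole pipeline is testable
    without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
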