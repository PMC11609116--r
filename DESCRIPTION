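Package: elscape
Title: Energy-Landscape Analysis of Task-State fNIRS Brain Dynamics
Version: 0.1.0
Authors@R: person("elscape", "maintainers", email = "elscape@example.org",
    role = c("aut", "cre"))
Description: Channel-level, data-driven energy-landscape analysis of
    multichannel functional near-infrared spectroscopy (fNIRS) recordings.
    Implements CANDECOMP/PARAFAC tensor decomposition for channel selection,
    mean-threshold binarization of hemodynamic time series, pairwise
    maximum-entropy (Ising) model fitting by pseudo-likelihood or exact
    gradient, construction of the energy landscape on the state hypercube
    with local minima, basins of attraction and Metropolis random-walk dwell
    statistics, group-level statistics over landscape features, and a
    radial-basis-kernel maximum-margin classifier with leave-one-out
    cross-validation for depression detection.  A synthetic-cohort generator
    with planted group differences makes every stage testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
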