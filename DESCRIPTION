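Package: rrscurve
Title: Cross-Validated Repeated Random Sampling for Classifier Learning Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extrapolates supervised-classifier error rates from small pilot
    datasets to larger cohort sizes. Error rates are estimated at a grid of
    training-set sizes by repeated random subsampling nested inside a
    stratified K-fold rotation of training and testing pools, screened for
    significance against a permutation null of label-randomized classifiers,
    and fitted with a constrained three-parameter inverse power law whose
    intercept estimates the Bayes error. Includes a traditional fixed-split
    repeated-random-sampling baseline, interquartile-range stability
    summaries, leave-one-out validation on larger cohorts, patient-level
    (grouped) two-stage sampling for pixel- and voxel-level data, and a
    two-class Gaussian synthetic data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    MASS,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    class,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
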