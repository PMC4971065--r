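Package: EEGmicrostates
Title: EEG Microstate Segmentation and Temporal Sorting of fMRI Resting-State Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Resting-state EEG microstate analysis with coupling to fMRI
    resting-state network (RSN) time courses. Implements global field power
    (GFP) peak extraction, polarity-invariant modified K-means clustering of
    peak topographies with a cross-validation criterion for the number of
    microstate classes, canonical A-D labeling, topographic permutation
    testing (TANOVA), competitive backfitting with the full set of temporal
    microstate parameters (mean duration, occurrence, time coverage, global
    explained variance, transition probabilities), repeated-measures
    multivariate group comparison with covariates, and HRF-convolved
    regressor construction for temporal sorting of RSN component time
    courses. A seeded two-group synthetic-data generator with known
    microstate ground truth and a known microstate-to-RSN coupling matrix
    makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Electrophysiology, TimeCourse, Clustering, StatisticalMethod
RoxygenNote: 7.3.3
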