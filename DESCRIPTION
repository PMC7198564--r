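Package: rersim
Title: Simulation and Multivariate Analysis of Rapid Event-Related Monkey fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Linear-systems tools for comparing BOLD and MION contrast
    mechanisms in rapid event-related non-human-primate fMRI, together with
    a general-linear-model and representational-similarity pipeline for
    region-of-interest voxel time series. Provides gamma-family impulse
    response models with smooth-onset variants, stimulus-schedule
    generators (alternating, rapid event-related, block), periodogram-based
    full-spectrum dominance tests and a peak-ratio sweep, per-run GLM
    estimation with fixation- and motion-based trial censoring,
    cross-validated Mahalanobis (crossnobis) distance matrices with
    split-half folds, and a seeded synthetic ROI data generator with
    planted ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
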