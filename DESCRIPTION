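Package: ethogaze
Title: Ethogram-Based Gaze and Neural Encoding Analysis for Naturalistic
    Viewing Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing information-foraging ("channel surfing")
    experiments in which subjects choose among video-viewing options and
    freely view annotated naturalistic video. Provides an ethogram data
    model (frame-wise scoring of leveled states and binary events, and
    derivation of nested binary analysis variables), gaze-focus processing
    (boxcar downsampling, video-normalised coordinates, in-frame flags) with
    distance-capped gaze-consistency and gaze-typicality statistics, a task
    simulator with adaptive menu weighting and menu-validity constraints,
    elastic-net penalized GLMs with per-coefficient penalty factors,
    20-fold cross-validation with the one-standard-error rule and
    permutation false-discovery checks, a ranked two-alternative choice
    utility model, Poisson spike-count encoding models with
    timecourse/drift offsets and lagged regressors, and a synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
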