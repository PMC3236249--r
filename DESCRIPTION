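Package: raicarn
Title: Reproducibility Ranking and Permutation Inference for Spatial ICA Components
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Objective reproducibility analysis for spatial component maps,
    typically independent component analysis (ICA) maps from resting-state
    fMRI. Components from repeated decompositions are matched across runs by
    greedy maximisation of absolute spatial correlation, each matched
    component receives a normalized reproducibility score, and p-values are
    assigned against a permutation null in which component labels are
    randomly re-partitioned into pseudo-runs. Includes a subject-subsampling
    planner for group ICA controlling pairwise subject co-occurrence, a
    Student-t/Gamma mixture model for thresholding group-average statistic
    maps, a synthetic multi-run generator with planted ground truth, and a
    temporal-concatenation group-ICA harness with injectable unmixing
    backends.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
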