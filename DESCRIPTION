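Package: icnscore
Title: Intrinsic Connectivity Network Brain-State Scoring for Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("ICN", "Maintainers", email = "icnscore@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for multivariate pattern-recognition
    analysis of resting-state fMRI: temporal/spatial preprocessing of
    pre-aligned 4-D scans, group independent component analysis with
    subject-specific intrinsic-connectivity-network back-reconstruction,
    a nested leave-one-out support-vector-machine ensemble with anchored
    forward component selection producing signed brain-state scores,
    sign-flip permutation tests on voxelwise Fisher-z connectivity, and
    covariate-adjusted rank correlation between scores and normalized
    treatment response. Includes a synthetic cohort generator emulating a
    patient/control treatment study so every stage is testable without
    scanner data, and a minimal NIfTI-1 reader/writer.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
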