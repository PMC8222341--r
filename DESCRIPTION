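Package: hepatocad
Title: Computer-Aided Grading of Liver Tumors from Four-Phase
    Contrast-Enhanced Volumes
Version: 0.1.0
Authors@R:
    person("hepatocad", "developers", email = "hepatocad@example.org",
           role = c("aut", "cre"))
Description: Extracts morphological (spherical-harmonic surface
    reconstruction errors), textural (first-order histogram,
    rotation-invariant gray-level co-occurrence and run-length), and
    functional (wash-in/wash-out enhancement slope) markers from
    four-phase contrast-enhanced abdominal volumes with binary tumor
    masks, selects informative markers by stepwise and random-forest
    impurity criteria, and grades tumors on the LR1-LR5 scale with a
    two-stage random-forest classifier evaluated under leave-one-subject-out
    and stratified k-fold cross-validation.  Includes a grade-conditioned
    phantom generator so the whole pipeline is testable without clinical
    data, minimal NIfTI-1 input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    FNN,
    jsonlite,
    Matrix,
    quadprog,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
SystemRequirements: C++17
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
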