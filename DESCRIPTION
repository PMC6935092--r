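Package: kelmplus
Title: Privileged-Information Kernel Extreme Learning Machines for
    ROI-Based Brain Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies subjects into blood-pressure grades from regional
    brain-morphometry features (gray/white-matter and cerebrospinal-fluid
    volumes, cortical thickness and surface area over the 90-region AAL
    parcellation, plus single-subject inter-regional cortical-thickness
    networks). The classifier core is a kernel extreme learning machine
    trained under the learning-using-privileged-information paradigm
    (KELM+): each of five classifiers pairs one main feature type with a
    distinct privileged feature type available only during training, inputs
    are lifted through an empirical kernel map, and predictions are fused
    by majority vote. Includes per-subject feature normalization, two-stage
    feature selection (t-test filter then mutual-information ranking),
    repeated stratified cross-validation with seven confusion-matrix
    metrics, selection-frequency reports, and a synthetic cohort generator
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
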