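Package: inceptr
Title: Simulation and Analysis of Closed-Loop Decoded Neurofeedback Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to simulate and analyse multi-session closed-loop decoded
    neurofeedback ("inception") experiments at desk scale. A synthetic-data
    generator stands in for the scanner, producing parcellated multivoxel
    recognition and feedback runs with known ground truth. The package
    implements real-time (running) and offline z-scoring, pairwise
    L2-regularised logistic decoders with graded evidence, data-driven
    feedback-ROI construction (reference-cohort parcel ranking, top-N
    mega-ROI, greedy backward elimination), the per-TR wobble/reward feedback
    engine with an adaptive staircase, logistic psychometric fitting for
    categorical perception, behavioural and neural integration indices, and
    group-level bootstrap inference, so that the whole five-session protocol
    can be replicated end to end on simulated cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr,
    RNifti,
    withr,
    yaml
Suggests:
    glmnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
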