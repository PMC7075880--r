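Package: reinstater
Title: Behavioral Scoring and Scene-Reinstatement Decoding for AB-AC
    Memory-Integration Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for associative-inference (AB-AC) memory
    experiments combining behavior and fMRI pattern decoding. Converts
    three-part memory-test responses (confidence-rated item recognition,
    rater-scored associative recall, two-alternative associative
    recognition) into a 0-9 composite memory score; computes the analytic
    guessing chance level of that score from lure false-alarm behavior,
    with a Monte-Carlo oracle; bins trials by rated congruency and
    reported reactivation and runs one-sample tests and 2x3
    repeated-measures ANOVAs; trains a cross-validated, permutation-tested
    scene-versus-face logistic decoder on localizer blocks and applies it
    to encoding events to read out per-trial scene-reinstatement
    probability; and simulates behavioral tables and block-design voxel
    patterns with known ground truth so the whole pipeline is testable
    without scanner data.
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
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
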