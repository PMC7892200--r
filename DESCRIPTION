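Package: fpl
Title: Analysis and Simulation of Formant Feedback Perturbation Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditory feedback perturbation experiments on vowel
    formants: deterministic trial-schedule generation for unpredictable
    (mid-utterance and whole-utterance) and consistent (adaptation)
    first-formant perturbation sessions; a feedback + feedforward control
    simulator producing per-trial F1 tracks with known ground truth;
    within-trial normalization, onset-latency detection and peak percent
    compensation; across-trial sensorimotor adaptation trajectories and
    late-hold adaptation percentages; within-trial response dynamics across
    adaptation phases; and the associated inferential layer (one-sample
    t-tests, random-intercept regressions, factorial mixed models, session
    order checks) with plain-text serialization of every result.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    MASS,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
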