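Package: headingflow
Title: Optic-Flow Heading Perception, an MT-MST Population Model, and
    Simulated Age-Related Cell Loss
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying translational heading perception from optic
    flow. Generates random-dot translational flow stimuli (including motion
    coherence noise and off-axis stereoscopic projection), implements a
    two-layer MT to MST population model that decodes heading by a subspace
    least-squares flow-matching criterion with fixed (untrained) weights,
    simulates age-related neuronal loss by random deactivation of MST-layer
    units, and provides Monte-Carlo chance-performance baselines plus the
    behavioral accuracy and precision analysis pipeline (regression fits,
    heading error, per-heading precision, Mann-Whitney comparisons with
    Benjamini-Hochberg correction) together with a synthetic-cohort generator
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
    Matrix,
    purrr,
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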