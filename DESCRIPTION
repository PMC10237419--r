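Package: splitbelt
Title: Split-Belt Treadmill Adaptation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for split-belt treadmill gait adaptation:
    synthesis of stride-level outcome series and raw marker/force signals
    for a two-group cohort with known double-exponential adaptation
    structure; low-pass filtering, foot-strike detection and stride
    segmentation of raw signals; step length asymmetry and per-leg
    mechanical work rates from ground reaction forces via the individual
    limbs (point-mass) method; one- and two-exponent nonlinear
    mixed-effects adaptation models with a participant-level random
    plateau fitted by exact marginal maximum likelihood; AIC/BIC/LRT
    model selection; and group-comparison statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
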