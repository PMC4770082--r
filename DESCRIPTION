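Package: embryomech
Title: Micropipette-Aspiration Mechanics and Viability Prediction for One-Cell Embryos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting the developmental potential of zygotes from
    their bulk viscoelastic properties measured by micropipette aspiration.
    Provides closed-form creep responses and nonlinear least-squares fitting
    for a family of lumped-parameter spring-dashpot models (Maxwell,
    Kelvin-Voigt, Zener, modified Zener, two-arm Wiechert), cross-correlation
    template tracking of the aspiration depth in bright-field video,
    SVM-RBF viability classification with Monte-Carlo cross-validated ROC/PR
    evaluation and greedy forward feature selection, circumferential
    cortical-granule scoring of confocal z-stacks, a battery of the
    associated two-sample statistical tests, and seeded synthetic-data
    generators (embryo cohorts, aspiration traces, aspiration videos and
    confocal stacks) that emulate the measurements end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    EBImage,
    deSolve,
    minpack.lm,
    nortest,
    tiff,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
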