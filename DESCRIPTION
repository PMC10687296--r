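Package: annL36
Title: Taguchi Orthogonal-Array Neural Networks for Chronic Disease
    Prevalence Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Derivative-free training of a fixed 23-weight feed-forward
    neural network by iterated evaluation over the mixed-level Taguchi
    orthogonal array L36(2^11 x 3^12), with winner-centred level
    refinement and an improvement-based stopping rule.  Includes fuzzy,
    logarithmic, min-max and z-score coding of model inputs and targets,
    MMRE-based evaluation with Pearson, Spearman and cubic-fit
    determination coefficients, gain-ratio attribute scoring, closed-form
    2x2 odds-ratio and two-proportion statistics, decision-tree, support
    vector regression and radial-basis-function baselines behind a
    uniform contract, and a synthetic survey-cohort generator emulating
    the stratified prevalence structure of the Serbian national
    non-communicable disease surveys of 2013 and 2019, so that the full
    model-comparison experiment is runnable without access to the
    original microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    rpart,
    e1071,
    kernlab
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
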