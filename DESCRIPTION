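Package: histbias
Title: Adaptive Stimulus-History Biases in Perceptual Choice and Motor Preparation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how the recent history of stimuli and
    choices biases perceptual decisions, and how that bias couples to
    action-selective motor-cortical beta-band lateralization. Implements a
    lapse-rate logistic psychometric model with additive history kernels,
    cross-validated model-order selection, cross-fitted single-trial bias
    estimation, choice-balanced subsampling of bias bins, single-trial
    regressions of bias and evidence on the amplitude, baseline level and
    build-up slope of lateralization time courses, and the resampling and
    circular statistics used alongside them. A synthetic-data module
    generates Markov stimulus sequences, model-governed agent choices and
    lateralization epochs with known ground truth for parameter-recovery
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    stats,
    generics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
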