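Package: radarscreen
Title: Eye-Tracking Screening for Reading Difficulties from Silent-Reading Scanpaths
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A screening pipeline for reading difficulties built on silent-reading
    eye movements. Raw 60 Hz gaze samples are clustered into fixations with a
    dispersion (I-DT) algorithm, saccades are extracted with a speed criterion,
    and twelve reading parameters are computed per reader: the exponential tail
    (tau) of an ex-Gaussian fit to fixation durations, saccade-length quartiles,
    short backward refixations, total fixation count, word-skipping and multiple
    first-pass fixation counts, and word-length-binned gaze-difficulty counts
    scored against control-population word norms. Parameters are evaluated by
    ROC area and test-retest stability, and combined into a Total Reading Score:
    the posterior probability of belonging to the control class under two-class
    multivariate Gaussian densities, validated by leave-one-out cross-validation
    and summarised as likelihood ratios and prevalence-conditional post-test
    probabilities. A generative model of reading scanpaths for typical and
    dyslexic reader profiles makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
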