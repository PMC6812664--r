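Package: disturbsim
Title: Monte-Carlo Study of Disturbance-Induced Threshold Associations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates virtual cohorts in which two normally distributed
    true traits (e.g., intelligence and creative potential) are both
    attenuated by a shared beta-distributed disturbance factor, and tests
    whether the resulting observed scores exhibit a spurious threshold-like
    association. Provides a segmented (broken-line) regression fitter with
    exhaustive breakpoint profiling, a three-criterion verification rule
    for the threshold hypothesis (significant breakpoint, positive and
    significant correlation below it, significantly stronger correlation
    below than above), Fisher r-to-z comparison of correlations, and an
    experiment orchestrator that estimates verification probabilities by
    logistic regression across sample sizes and disturbance skewness
    profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
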