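Package: crtkit
Title: Design, Derivation and Verification of Cognitive Relevance Transforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for re-targeting image-classification label spaces to a
    human population. Provides statistically powered design of crowd-sourced
    categorization studies (two-proportion, chi-squared independence,
    binomial and one-way ANOVA power solvers), binomial consensus aggregation
    of per-subject forced-choice answers, derivation of a population-specific
    category transform (merge, separate, rename) from grouping and free-text
    labeling responses via k-modes clustering with elbow model selection and
    a text-cleaning chain, application of the transform to human and machine
    confusion matrices with macro Top-1/precision/recall/F1 reporting, and
    statistical verification against random-transform nulls with the
    Wilcoxon signed-rank test. A synthetic-respondent simulator with planted
    perceptual clusters makes every stage testable without any crowd
    platform or image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    mclust
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
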