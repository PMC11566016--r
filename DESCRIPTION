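Package: remdiff
Title: Pattern-Similarity Analysis of Sleep-Dependent Hippocampal Memory Differentiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring experience- and sleep-dependent change in
    item-level neural representations with functional MRI pattern similarity.
    Implements the statistical-learning design with prediction-violation and
    nonviolation pair conditions, peak-hemodynamic snapshot extraction from
    4D functional data, pairmate Fisher-z pattern similarity and neural
    differentiation scores, a randomization test of item specificity,
    prediction-differentiation coupling, face-integration controls, planned
    group contrasts with pooled variance, hypnogram-based sleep architecture
    metrics and spindle densities, and a synthetic-data generator with
    planted representational effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    car,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
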