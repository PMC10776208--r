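Package: structcpm
Title: Structural Connectome-Based Predictive Modeling of Cognitive Performance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Connectome-based predictive modeling (CPM) for structural brain
    networks weighted by streamline (fiber) counts. Implements edge-wise
    Spearman screening, summary connectivity scores, linear prediction models
    with leave-one-out cross-validation and permutation testing, brain mapping
    of cross-validated predictive edges and critical network nodes, covariate
    screening and model-family comparison, and normative deficit
    classification against a matched control group. Includes a synthetic
    cohort generator with recorded ground truth that emulates
    network-block-structured fiber-count matrices with hemispheric lesion
    effects, for testing and power exploration.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
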