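Package: rfqa
Title: Random Forest Quality Assessment of Predicted Protein Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decides whether candidate three-dimensional protein models from
    template-free structure prediction are in the correct fold (TM-score at
    least 0.5). Combines predicted-contact satisfaction, local and spectral
    predicted contact map alignment scores, externally supplied single-model
    quality scores, an ensemble consensus score, and per-target ensemble
    summary statistics into a 58-feature random forest classifier whose vote
    fraction is reported in four confidence tiers. Includes the evaluation
    framework (per-tier selection reports, ROC/AUC, false-positive-rate
    thresholding, top-10 convergence baseline), an iterative
    generate-and-assess protocol, and a fully synthetic benchmark generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    randomForest,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
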