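Package: pvpkit
Title: Phage Virion Protein Prediction from Fused Sequence Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-based prediction of phage virion (structural) proteins.
    Encodes protein, DNA or RNA sequences as k-tuple composition vectors
    (all i-mer frequencies for i = 1..k) and proteins additionally as the
    classical 188-dimensional descriptor (20 amino-acid composition values
    plus 168 composition/transition/distribution features over eight
    physicochemical properties). Features are ranked by boosted
    decision-stump (AdaBoost) importance, the top-n k-mer features are fused
    with the 188-dimensional block, and a linear model is trained by
    least-mean-squares stochastic gradient descent. Includes stratified
    k-fold cross-validation and holdout evaluation with sensitivity,
    specificity, accuracy and Matthews correlation coefficient, a synthetic
    labelled-sequence generator for end-to-end testing, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
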