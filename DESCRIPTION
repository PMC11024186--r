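Package: rfslda
Title: Randomized Feature Selection Based Semi-Supervised Latent
    Dirichlet Allocation for Microbiome Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-supervised classification of subjects by health status from
    taxon count tables. Fits a latent Dirichlet allocation mixed-membership
    model to microbiome read counts by collapsed Gibbs sampling, matches the
    latent topics to fuzzy health-status labels by exhaustive enumeration of
    bijections scored with a class-weighted true-positive-rate metric, and
    wraps the whole fit in a randomized add/remove/swap search over taxon
    subsets to select the features that drive classification. Includes
    abundance/prevalence concordance filtering of taxa, SMOTE plus
    cluster-based undersampling for unbalanced classes, within-group
    similarity labelling from topic proportions, stratified train/test and
    k-fold evaluation protocols, and a Dirichlet-multinomial corpus simulator
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
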