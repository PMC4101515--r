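Package: metamiss
Title: Missing-Value Substitutes for GC-MS Metabolomics and Their Downstream Impact
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Benchmarks five missing-value substitutes for GC-MS metabolomics
    feature tables (zero, mean, median, k-nearest-neighbour and iterative
    random-forest imputation) and quantifies their influence on downstream
    multivariate analysis: autoscaling, cross-validated PCA scree analysis
    with Q2, Ward-linkage hierarchical clustering with a purity score, and
    bootstrap-validated PC-LDA and PLS-DA classification. Includes a
    synthetic-data generator emulating skewed multi-class metabolite
    intensity tables with controlled missingness mechanisms (completely at
    random and limit-of-detection censoring) so every stage carries ground
    truth for imputation error (NRMSE).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
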