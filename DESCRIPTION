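Package: magiclasso
Title: Missingness Adapted Group Informed Clustered LASSO
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts an unmeasured phenotype from thousands of partially
    observed variables under block-wise, non-random missingness.  Variables
    are profiled and filtered for sparsity and for balance between the
    measured (training) and unmeasured (prediction) subject sets, clustered
    by missingness structure with average-linkage hierarchical clustering,
    and selected by iterated cross-validated group-LASSO fits within
    clusters.  A final model is built stepwise over variables ordered by
    completeness and chosen by hold-out correlation.  Includes simulation
    machinery for complete-case collapse under random plus block-wise
    missingness and for end-to-end phenotype-prediction studies on
    synthetic multivariate data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
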