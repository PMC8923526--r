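Package: anthemet
Title: Predicting Greenhouse Tomato Anthesis Rate from Leaf Metabolome Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting the anthesis (flowering) rate of greenhouse
    tomato from widely targeted leaf metabolome profiles. Implements the full
    analysis chain: preprocessing of targeted-metabolomics peak tables
    (signal-to-noise detection filtering against extraction blanks, internal
    standard normalization, standardization and 0-1 scaling), derivation of
    anthesis rates from cumulative flower counts with nonparametric group
    comparisons, LASSO linear regression by cyclic coordinate descent with a
    penalty sweep, 10-fold cross-validation and elbow-based selection of
    predictor metabolites, cross-dataset re-validation of the selected panel,
    and downstream marker characterization by principal component analysis,
    hierarchical clustering with cophenetic linkage selection,
    correspondence-analysis association networks, and a diurnal-stability
    screen. A synthetic-data generator with known ground truth emulates the
    study design (2-hourly 24-h leaf sampling over four weeks in two
    cultivars) so the whole pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
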