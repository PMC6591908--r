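Package: metaboclust
Title: Chemocentric Clustering and Trait Classification for Untargeted
    Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A chemocentric workflow for case/control untargeted
    metabolomics: preprocessing of intensity tables (half-minimum
    imputation, total quantity normalization, log2 transform,
    auto-scaling, covariate adjustment), Monte Carlo permutation t-tests
    with Benjamini-Hochberg correction, clustering of metabolites by
    chemical structure (MACCS fingerprints, correlated-bit filtering,
    Soergel distance, average linkage, silhouette-selected number of
    clusters), Fisher-exact cluster enrichment and hypergeometric pathway
    over-representation tests, and per-cluster multi-metabolite
    classifiers tuned by grid search with leave-one-out cross-validation,
    ROC threshold selection and external validation. Includes a synthetic
    cohort-pair generator with planted chemical-family signals, covariate
    effects, left-censored non-detects and batch shifts for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ChemmineOB,
    e1071,
    randomForest,
    xgboost,
    mixOmics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    mclust,
    optparse,
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'methods-accessors.R'
    'chemstruct.R'
    'classify.R'
    'clustering.R'
    'diffstats.R'
    'io.R'
    'pipeline.R'
    'predict.R'
    'preprocess.R'
    'synthdata.R'
    'utils.R'
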