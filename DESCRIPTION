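Package: glycostrat
Title: Unsupervised Glycometabolic Stratification and Gut-Microbiome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stratifies glycometabolic cohorts by k-medoids clustering of 16
    clinical variables (OGTT glucose and insulin curves, HbA1c, anthropometrics,
    lipids), selects the number of clusters by mean silhouette width, assesses
    cluster stability by bootstrap Jaccard coefficients, and characterises the
    gut microbiome of the resulting clusters: alpha diversity, phylogenetic
    isometric log-ratio (PhILR) ordination with PERMANOVA, cluster-specific
    amplicon sequence variants (Wilcoxon rank-sum with Benjamini-Hochberg FDR
    and log2 fold-change thresholds), per-cluster Pearson co-abundance networks
    with co-abundance groups (CAGs), arcsine-square-root linear-model
    associations between features and clinical phenotypes, and one-vs-rest
    random-forest classifiers evaluated by leave-one-out cross-validation.
    Includes a synthetic cohort generator so the whole pipeline is testable
    without access to patient data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    MASS,
    ape,
    vegan,
    randomForest,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    picante,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
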