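Package: metabscreen
Title: Serum Metabolome Screening Analysis with Nested Cross-Validated Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Panel-aware preprocessing, univariate statistics and multinomial
    signature classification for targeted serum metabolomics in lung-cancer
    screening cohorts. Provides a 408-analyte 10-class panel registry,
    plate-exported concentration table I/O, a two-cohort synthetic data
    generator with planted group, cohort and plate effects, the normalization
    chain (missingness partition, k-nearest-neighbour imputation,
    truncated-normal below-LOD replacement, log2 transform, parametric
    empirical-Bayes batch correction, UMAP embedding), a cross-cohort rank
    statistics battery (Kruskal-Wallis with eta-squared, Conover-Iman post hoc
    with Pallant r, Jonckheere-Terpstra trend, Lancaster combination,
    Benjamini-Hochberg FDR, presence/absence chi-square), and a nested
    cross-validated multinomial logistic signature classifier with forward-BIC
    selection, consensus feature ranking and elbow cut.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    matrixStats,
    uwot,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    nnet,
    pROC,
    sva,
    truncnorm
Config/testthat/edition: 3
RoxygenNote: 7.3.3
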