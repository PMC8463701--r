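Package: evotrait
Title: Evolutionarily Informed Machine Learning for Transcriptome-to-Trait
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts quantitative phenotypes from transcriptome responses
    using evolutionarily conserved differential expression as a biologically
    principled feature-reduction step. Implements leave-one-genotype-out
    negative-binomial differential expression with upper-quartile
    normalization, cross-species homolog intersection of consensus gene
    lists, gradient-boosted trait prediction benchmarked against control
    feature sets, feature-importance aggregation, tree-ensemble regulatory
    network inference with hub ranking, phenotype-panel statistics, and a
    ground-truthed synthetic data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    edgeR,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
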