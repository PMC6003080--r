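Package: taxhfe
Title: Taxonomy-Aware Hierarchical Feature Engineering for Microbiome
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements hierarchical feature engineering (HFE) for
    case-control classification of 16S rRNA microbiome profiles. Starting
    from an OTU abundance table and a Greengenes-style taxonomy, the
    feature space is enlarged with taxon-aggregated relative abundances at
    every rank and then pruned by parent-child Pearson correlation
    filtering, information-gain filtering under Fayyad-Irani MDL
    supervised discretization, and a dedicated filter for OTUs with
    incomplete lineages. Includes a leakage-free per-fold cross-validation
    harness with pluggable classifiers and a synthetic-data generator that
    plants case/control effects on chosen clades.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    biomformat,
    pROC,
    rpart,
    randomForest,
    e1071
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
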