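Package: exocerna
Title: Plasma-Exosome ceRNA Network Biomarker Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for competing endogenous RNA (ceRNA) biomarker
    discovery from plasma-exosome expression profiles: two-group differential
    expression of lncRNA, miRNA and mRNA with a fold-change and p-value gate;
    directional lncRNA-miRNA-mRNA network construction by target intersection
    and reverse miRNA identification; partial correlation of network features
    with clinical severity scores controlling demographic covariates;
    hypergeometric over-representation analysis; degree-based hub ranking on a
    score-thresholded protein-protein interaction subgraph; and empirical
    ROC/AUC diagnostics for single markers and logistic-combined
    lncRNA-miRNA-mRNA axes. Ships a synthetic-data generator that plants
    ceRNA triplets with configurable effect sizes so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
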