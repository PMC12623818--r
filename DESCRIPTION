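Package: exococa
Title: Exosome Multi-Omics Subtype Stratification via Cluster-of-Clusters
    Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible re-implementation of an exosome multi-omics
    stratification workflow for chronic pancreatitis: per-platform Monti
    consensus clustering (PAM k-medoids on Pearson-correlation distance with
    resampling, CDF-area, PAC and silhouette diagnostics), cluster-of-cluster
    (COCA) integration with a proportional CDF-area-increase rule for choosing
    the cluster number, exocrine/endocrine gene-signature scoring by per-sample
    medians, a diagnostic classifier built from a univariate logistic screen,
    bootstrap stability selection, LASSO reduction and a grid-searched
    resilient-backpropagation neural network, and a miRNA-mRNA key-pair filter
    combining negative Pearson correlation with ordered-group monotone-trend
    screening. A synthetic cohort generator with planted subtypes, signature
    genes and miRNA-mRNA couplings makes every stage testable without access
    to patient sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    glmnet,
    yaml,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    fgsea,
    withr
Config/testthat/edition: 3
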