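Package: cernaPivot
Title: lncRNA-mRNA ceRNA Network Inference with Pivotal-Node Calling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to reconstruct lncRNA-mRNA competing-endogenous-RNA
    (ceRNA) interaction networks from case-control bulk RNA-seq expression
    profiles. Covers FPKM normalization, differential-expression screening,
    machine-learning evaluation of sample separability (PCA, K-means,
    Gaussian mixture models), hypergeometric gene-set over-representation
    with expression-trend scoring, correlation-plus-miRNA-target network
    construction, degree/betweenness/closeness pivotal-node calling, and
    2^-ddCt relative quantification of qPCR validation plates. Includes a
    negative-binomial simulator that plants differential expression, a
    co-regulated hub-lncRNA module and matched miRNA-target tables so the
    whole pipeline can be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0), SummarizedExperiment
Imports: methods, stats, utils, tools, S4Vectors, igraph, jsonlite, yaml
Suggests: testthat (>= 3.0.0), mclust, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Transcriptomics, GeneExpression, DifferentialExpression,
    Network, NetworkInference, RNASeq
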