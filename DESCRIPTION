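Package: padnet
Title: Pathway Association and Genetic Network Discovery for Case-Control SNP Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: End-to-end toolkit for pathway- and network-level analysis of
    case-control genome-wide SNP data. Implements genotype quality control
    (missingness, minor allele frequency and Hardy-Weinberg filters,
    modal-genotype imputation, sliding-window tag-SNP pruning, flank-based
    SNP-to-gene mapping), the logistic kernel machine regression SNP-set
    score test with a chi-square-mixture null distribution, pairwise
    SNP-by-SNP epistasis scanning with a logistic interaction model,
    construction of protein-protein-interaction-supported epistatic gene
    networks with scale-free testing, Poisson hub calling and Newman
    modularity decomposition, and depth-filtered hypergeometric Gene
    Ontology enrichment of network modules. A seeded synthetic-data
    generator with planted pathway and interaction effects makes the whole
    pipeline testable without access-controlled genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    igraph,
    jsonlite,
    yaml,
    pracma,
    fgsea,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
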