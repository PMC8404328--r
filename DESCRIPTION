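Package: modflow
Title: Multi-Omic Disease Module Detection and GWAS-Based Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection, scoring and integration of multi-omic disease modules
    on gene-gene interaction networks. Provides differential seed-gene
    selection, three classes of network module detection (differentially
    expressed maximal cliques, seed-based DIAMOnD expansion, co-expression
    clustering), gene-based GWAS set scoring by chi-square fusion of SNP
    p-values, consensus and intersection integration of modules across
    datasets and omics, and the benchmark statistics used to assess modules
    (Fisher's method meta p-values, excess-significance binomial tests,
    enrichment odds ratios, permutation overlap tests, betweenness
    diagnostics). A synthetic-data generator plants a ground-truth module in
    a random network together with matched expression, methylation, GWAS and
    risk-factor gene-set signal, so the whole workflow is testable end to
    end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Matrix,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
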