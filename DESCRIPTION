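Package: sRNAcoexp
Title: Small RNA Co-Expression Networks and Regulator Triage for
    Reproductive-Tissue Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis toolkit for nominating small RNAs (miRNAs, snRNAs,
    snoRNAs) as candidate regulators of gene expression from bulk RNA-seq of
    multiple tissues. Implements RPKM normalization with mixed-model removal
    of sequencing-library effects, empirical-Bayes moderated t differential
    expression per pairwise tissue comparison, regulatory impact factor (RIF)
    scoring of differentially expressed small RNAs, partial correlation and
    information theory (PCIT) co-expression network inference with hub and
    betweenness-centrality analysis, miRNA seed-site scanning (8mer, 7mer-m8,
    7mer-A1, 6mer) with intermolecular duplex minimum-free-energy
    confirmation, and hypergeometric over-representation with kappa-score
    term clustering. A synthetic-data generator with planted differential
    expression, regulator-target co-expression, and seed sites makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    igraph,
    lme4,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma
Config/testthat/edition: 3
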