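Package: cernet
Title: Competing Endogenous RNA Network Inference from Expression Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers lncRNA/circRNA-miRNA-mRNA competing endogenous RNA (ceRNA)
    networks from paired case/control expression profiles. Provides quantile
    normalization and fold-change/t-test differential expression screening,
    canonical miRNA seed-site prediction (6mer, 7mer-A1, 7mer-m8, 8mer) on
    linear and circular transcripts, target-pair intersection through shared
    miRNAs, cross-validation against a curated miRNA list, Pearson-correlation
    ceRNA pair selection, network assembly with Cytoscape-compatible export,
    degree-based hub-gene ranking on protein-protein interaction edge lists,
    and Fisher's-exact gene-set over-representation analysis. A synthetic-data
    generator plants known differential-expression effects and ceRNA triples
    so every pipeline stage can be validated against a recoverable ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    igraph,
    limma,
    Biostrings,
    fgsea,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
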