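Package: bicext
Title: Biclique Extension for Predicting Missing Compound-Protein Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts missing links in bipartite compound-protein interaction
    (CPI) networks by maximal biclique enumeration and biclique extension: a
    compound (or protein) adjacent to all but one member of one side of a
    maximal biclique is predicted to interact with the remaining member.
    Includes readers for STITCH-style link tables and KEGG KGML pathway files,
    network cleanup filters (heavy-atom, drug/antibiotic and degree-one
    removal), hold-out validation with TPR/FPR/F1 metrics, degree-preserving
    edge-switch randomization as a null model, molecular similarity
    characterization of bicliques (Tanimoto, local alignment scores, Cohen's
    d), hypergeometric pathway enrichment, and a planted-biclique synthetic
    network generator for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    xml2,
    Biostrings,
    ChemmineR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
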