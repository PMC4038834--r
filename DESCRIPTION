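Package: lepscan
Title: Detection, Annotation and Horizontal-Transfer Analysis of Lep1-Family
    Helitron Transposons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies non-autonomous Lep1-style Helitron transposable
    elements in nucleotide sequence, annotates their structural hallmarks
    (5'-TC and 3'-CTRY termini, the CTRR motif at the 3' end of the acquired
    sequence, the subterminal palindromic hairpin, and the A^T insertion
    junction without target-site duplication), measures inter-copy identity
    excluding indels, builds neighbor-joining trees with bootstrap support,
    assesses insertion polymorphism in silico with chimeric empty-site
    queries, and scores evidence of horizontal transfer between distantly
    related hosts. A seeded synthetic-genome simulator with full ground
    truth makes every stage of the pipeline testable.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    jsonlite,
    GenomicRanges,
    S4Vectors,
    IRanges,
    rtracklayer,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    BiocGenerics,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
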