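Package: mulescan
Title: Discovery and Characterization of Mutator-Like Transposable Elements
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for the discovery and structural characterization of
    Mutator-like transposable elements (MULEs) in genome assemblies, and for
    the analysis of yeast transposition-assay readouts. Includes a translated
    (six-frame) Smith-Waterman homology search for the conserved DDE
    transposase domain, terminal-inverted-repeat (TIR) and target-site
    duplication (TSD) annotation, subterminal tandem-repeat and terminal
    palindrome profiling, nonautonomous derivative discovery with Pack-MULE
    content classification, family clustering with bootstrap neighbor-joining
    phylogenies, insertion-site enrichment against a randomized null, and
    excision-footprint / reinsertion-site analytics. A synthetic-genome and
    assay-fixture generator provides fully specified ground truth for
    closed-loop validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    withr,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
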