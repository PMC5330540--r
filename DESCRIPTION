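Package: secScan
Title: Selenocysteine tRNA Gene Detection with Covariance Models
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects selenocysteine tRNA (tRNA-Sec) genes in genomic sequence.
    Builds domain-specific covariance models (profile stochastic context-free
    grammars) from structurally annotated seed alignments of the unusual
    tRNA-Sec cloverleaf (13-bp acceptor+T stem, long D-stem, long variable
    arm), scans both strands of a genome with a banded CYK parser, and
    annotates candidates: arm architecture and fold class (9/4, 8/5, 7/5),
    anticodon, discriminator base (G73), CCA tail, C-loop introns, and
    copy classification by compensatory versus disruptive pair mutations.
    Also provides an iterative model-refinement procedure, a genome-level
    sensitivity/specificity benchmark harness, a TGA-readthrough open reading
    frame screen for selenoprotein candidates, and a synthetic-genome
    generator for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
LinkingTo: Rcpp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
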