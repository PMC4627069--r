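Package: dloopmotif
Title: Motif Discovery and Characterization in Mitochondrial D-Loop Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-genomics toolkit for the vertebrate mitochondrial
    control region (D-loop). Extracts D-loop sequences from annotated
    mitochondrial genomes (including features wrapping the origin of a
    circular genome), reduces sequence redundancy by global-alignment
    percent identity, discovers ungapped motifs by expectation-maximization
    under the ZOOPS (zero-or-one occurrence per sequence) model on one or
    both strands, performs iterative profile-based homology search, and
    characterizes recovered motifs: conserved anchor triplets and spacer
    length, reverse-complement palindromy, strand merging of motif pairs,
    tandem copies with inter-copy distances, and per-column variant-density
    overlays. Ships a synthetic D-loop generator with planted ground truth
    so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
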