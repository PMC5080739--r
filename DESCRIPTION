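Package: vdjalign
Title: Whole-Locus Alignment and Annotation of V(D)J Recombination Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates T-cell-receptor and immunoglobulin repertoire reads by
    local alignment to a whole receptor locus (including introns and intergenic
    DNA) instead of V(D)J gene segments alone. Candidate alignments are produced
    by maximal-exact-match anchoring and chaining with a controllable extension
    gap ('breaklen'), reduced to an optimal set by greedy overlap filtering,
    refined with annotation-aware rules, and trimmed at optimal cut points with
    an exon bonus. Reads are then labelled with V, D, J, C and intergenic
    segments, CDR3 junctions are extracted from conserved cysteine and
    phenylalanine/tryptophan anchors, and each read is classified as a regular
    or non-regular recombination product. A synthetic locus and read simulator
    with per-read ground truth makes the whole pipeline testable offline, and a
    comparison tool tallies annotation agreement between two runs or tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    Rcpp,
    rlang,
    tibble,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
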