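Package: ConsStates
Title: Conservation-State Annotation of Genomes from Multi-Species Alignments
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Annotates a reference genome at single-nucleotide resolution into
    de novo conservation states by fitting a multivariate hidden Markov model
    to per-species align/match observations extracted from a multiple-species
    DNA sequence alignment (MAF). Each non-reference species contributes a
    three-way observation per base (aligns and matches the reference, aligns
    but mismatches, or does not align), modelled as independent multinomials
    per state. Includes scaled forward-backward inference with missing data,
    Baum-Welch training with per-iteration random segment subsampling,
    maximum-posterior decoding and segmentation merging, base-resolution fold
    enrichment of states for interval annotations (overlap, background-
    restricted and positional), state clustering with exact optimal leaf
    ordering, precision-recall evaluation machinery for scores and element
    sets, and a synthetic-alignment generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: HiddenMarkovModel, Alignment, Annotation, Software
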