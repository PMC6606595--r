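#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom GenomicRanges GRanges seqnames start end width strand mcols
#'   "mcols<-" reduce findOverlaps tileGenome
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits Rle runValue runLength
#' @importFrom GenomeInfoDb seqlengths seqlevels keepSeqlevels seqnames
#' @importFrom stats as.dist cor cutree hclust runif rbinom setNames sd
#' @importFrom utils read.table write.table head tail
NULL

#' Set of species in a reference-anchored multiple alignment
#'
#' Identifies the reference assembly and the fixed, ordered list of
#' non-reference species whose align/match observations are modelled. The
#' order is part of the data definition: every observation matrix, model and
#' binarized slice of one dataset uses the same species order.
#'
#' @slot reference single assembly name of the reference genome.
#' @slot others character vector of the N-1 non-reference species names,
#'   in fixed order.
#' @export
setClass("SpeciesSet",
  representation(reference = "character", others = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@reference) != 1L || !nzchar(object@reference))
      msg <- c(msg, "'reference' must be a single non-empty name")
    if (length(object@others) < 1L)
      msg <- c(msg, "at least one non-reference species is required")
    if (anyDuplicated(c(object@reference, object@others)))
      msg <- c(msg, "species names must be unique and distinct from the reference")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a SpeciesSet
#'
#' @param reference name of the reference assembly.
#' @param others ordered character vector of non-reference species.
#' @return A [SpeciesSet-class] object.
#' @examples
#' SpeciesSet("hg", c("chimp", "mouse"))
#' @export
SpeciesSet <- function(reference, others) {
  new("SpeciesSet", reference = as.character(reference),
      others = as.character(others))
}

#' Partition of a genome into fixed-length training slices
#'
#' Chromosomes are tiled left to right into half-open slices of
#' \code{sliceLength} bases (default 200 kb); the last slice of each
#' chromosome may be shorter. Slices are the unit of model training
#' (random subsets are drawn per Baum-Welch iteration), of decoding, and of
#' the train/test split in the precision-recall machinery.
#'
#' @slot chromLengths named numeric vector of chromosome lengths in bases.
#' @slot sliceLength slice width in bases.
#' @slot slices \code{GRanges} of the slices, in genome order, with a
#'   \code{sliceIndex} metadata column.
#' @export
setClass("GenomePartition",
  representation(chromLengths = "numeric", sliceLength = "integer",
                 slices = "GRanges"),
  validity = function(object) {
    msg <- NULL
    if (is.null(names(object@chromLengths)))
      msg <- c(msg, "'chromLengths' must be named by chromosome")
    if (object@sliceLength < 1L)
      msg <- c(msg, "'sliceLength' must be positive")
    if (any(object@chromLengths < 1))
      msg <- c(msg, "chromosome lengths must be positive")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a GenomePartition
#'
#' @param chromLengths named vector of chromosome lengths (bases).
#' @param sliceLength slice length in bases (default 200000).
#' @return A [GenomePartition-class] tiling each chromosome exactly.
#' @examples
#' GenomePartition(c(chr1 = 500e3, chr2 = 130e3), sliceLength = 200e3)
#' @export
GenomePartition <- function(chromLengths, sliceLength = 200000L) {
  chromLengths <- setNames(as.numeric(chromLengths), names(chromLengths))
  sliceLength <- as.integer(sliceLength)
  sl <- setNames(as.integer(chromLengths), names(chromLengths))
  tiles <- tileGenome(sl, tilewidth = sliceLength,
                      cut.last.tile.in.chrom = TRUE)
  mcols(tiles)$sliceIndex <- seq_along(tiles)
  new("GenomePartition", chromLengths = chromLengths,
      sliceLength = sliceLength, slices = tiles)
}

#' Per-base, per-species encoded alignment observations for one slice
#'
#' For each reference base i and non-reference species j the alignment
#' contributes one of three observations: the species aligns with a
#' nucleotide matching the reference (y=1, z=1), aligns with a different
#' nucleotide (y=1, z=0), or does not align with a nucleotide (y=0, z
#' missing). \code{z} uses \code{NA} for missing; positions covered by no
#' alignment block are all-unaligned, never dropped.
#'
#' @slot chrom,chromStart,chromEnd 0-based half-open slice coordinates.
#' @slot y integer T x (N-1) align indicators in \{0,1\}.
#' @slot z integer T x (N-1) match indicators in \{0,1,NA\}.
#' @slot species the [SpeciesSet-class] giving column order.
#' @export
setClass("ObservationMatrix",
  representation(chrom = "character", chromStart = "numeric",
                 chromEnd = "numeric", y = "matrix", z = "matrix",
                 species = "SpeciesSet"),
  validity = function(object) {
    msg <- NULL
    Tn <- object@chromEnd - object@chromStart
    if (nrow(object@y) != Tn)
      msg <- c(msg, "nrow(y) must equal slice length")
    if (!identical(dim(object@y), dim(object@z)))
      msg <- c(msg, "y and z must have identical dimensions")
    if (ncol(object@y) != length(object@species@others))
      msg <- c(msg, "one column pair per non-reference species required")
    if (!all(object@y %in% c(0L, 1L)))
      msg <- c(msg, "y must be binary")
    zv <- object@z[!is.na(object@z)]
    if (!all(zv %in% c(0L, 1L)))
      msg <- c(msg, "non-missing z must be binary")
    if (!identical(is.na(object@z), object@y == 0L))
      msg <- c(msg, "z must be missing exactly where y is 0")
    if (is.null(msg)) TRUE else msg
  })

#' Multivariate conservation-state hidden Markov model
#'
#' K hidden states over N-1 non-reference species. Each state k carries, per
#' species j, an align probability f[k,j] = P(species aligns) and a
#' conditional match probability g[k,j] = P(matches reference | aligns).
#' This two-Bernoulli parameterization is equivalent to a three-way
#' multinomial with p1 = f*g (align+match), p2 = f*(1-g) (align+mismatch),
#' p3 = 1-f (unaligned); see [emissionMultinomial()].
#'
#' @slot K number of states.
#' @slot species the [SpeciesSet-class].
#' @slot a length-K initial-state probabilities (applied at the first base
#'   of each independently modelled sequence).
#' @slot b K x K transition matrix, rows summing to 1.
#' @slot f K x (N-1) align probabilities.
#' @slot g K x (N-1) conditional match probabilities.
#' @slot fitInfo list of training diagnostics (log-likelihood trajectory,
#'   iteration count, seed) filled in by [baumWelch()].
#' @export
setClass("ConsModel",
  representation(K = "integer", species = "SpeciesSet", a = "numeric",
                 b = "matrix", f = "matrix", g = "matrix", fitInfo = "list"),
  validity = function(object) {
    msg <- NULL
    K <- object@K
    nsp <- length(object@species@others)
    if (length(object@a) != K) msg <- c(msg, "length(a) must equal K")
    if (!identical(dim(object@b), c(K, K)))
      msg <- c(msg, "b must be K x K")
    if (!identical(dim(object@f), c(K, nsp)) ||
        !identical(dim(object@g), c(K, nsp)))
      msg <- c(msg, "f and g must be K x (N-1)")
    ok01 <- function(x) all(x >= 0 & x <= 1)
    if (!ok01(object@a) || !ok01(object@b) || !ok01(object@f) || !ok01(object@g))
      msg <- c(msg, "all probabilities must lie in [0,1]")
    if (abs(sum(object@a) - 1) > 1e-6)
      msg <- c(msg, "initial probabilities must sum to 1")
    if (any(abs(rowSums(object@b) - 1) > 1e-6))
      msg <- c(msg, "transition matrix rows must sum to 1")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a ConsModel
#'
#' @param species a [SpeciesSet-class].
#' @param a initial-state probabilities (length K).
#' @param b K x K transition matrix.
#' @param f,g K x (N-1) align and conditional match probabilities.
#' @param fitInfo optional list of training diagnostics.
#' @return A [ConsModel-class].
#' @examples
#' sp <- SpeciesSet("hg", c("sp1", "sp2"))
#' ConsModel(sp, a = c(.5, .5), b = matrix(.5, 2, 2),
#'           f = matrix(.8, 2, 2), g = matrix(.7, 2, 2))
#' @export
ConsModel <- function(species, a, b, f, g, fitInfo = list()) {
  new("ConsModel", K = length(a), species = species, a = as.numeric(a),
      b = as.matrix(b), f = as.matrix(f), g = as.matrix(g),
      fitInfo = fitInfo)
}

#' Posterior state probabilities for one slice
#'
#' @slot chrom,chromStart,chromEnd slice coordinates (0-based half-open).
#' @slot values T x K matrix of marginal posterior state probabilities;
#'   rows sum to 1.
#' @slot loglik total log-likelihood of the slice under the model.
#' @slot loglikBackward log-likelihood recomputed from an independently
#'   scaled backward recursion (numerical cross-check).
#' @export
setClass("PosteriorMatrix",
  representation(chrom = "character", chromStart = "numeric",
                 chromEnd = "numeric", values = "matrix", loglik = "numeric",
                 loglikBackward = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@values) != object@chromEnd - object@chromStart)
      msg <- c(msg, "posterior rows must equal slice length")
    if (any(object@values < 0 | object@values > 1))
      msg <- c(msg, "posteriors must lie in [0,1]")
    if (any(abs(rowSums(object@values) - 1) > 1e-9))
      msg <- c(msg, "posterior rows must sum to 1 (1e-9)")
    if (is.null(msg)) TRUE else msg
  })

#' Per-base state labels for one slice
#'
#' @slot chrom,chromStart,chromEnd slice coordinates (0-based half-open).
#' @slot states integer vector of state labels in 1..K, one per base.
#' @slot K number of states of the generating model.
#' @export
setClass("StatePath",
  representation(chrom = "character", chromStart = "numeric",
                 chromEnd = "numeric", states = "integer", K = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@states) != object@chromEnd - object@chromStart)
      msg <- c(msg, "states length must equal slice length")
    if (length(object@states) &&
        (min(object@states) < 1L || max(object@states) > object@K))
      msg <- c(msg, "state labels must lie in 1..K")
    if (is.null(msg)) TRUE else msg
  })

#' Genome-wide conservation-state segmentation
#'
#' Maximal runs of constant state, as sorted, non-overlapping, 0-based
#' half-open intervals tiling each annotated chromosome.
#'
#' @slot runs \code{GRanges} with an integer \code{state} metadata column;
#'   adjacent runs on a chromosome carry different states.
#' @slot K number of states.
#' @export
setClass("Segmentation",
  representation(runs = "GRanges", K = "integer"),
  validity = function(object) {
    msg <- NULL
    st <- mcols(object@runs)$state
    if (is.null(st)) msg <- c(msg, "runs must carry a 'state' metadata column")
    else if (length(st) && (min(st) < 1L || max(st) > object@K))
      msg <- c(msg, "states must lie in 1..K")
    if (is.null(msg)) TRUE else msg
  })

#' Fold-enrichment table of states for external annotations
#'
#' Fold enrichment of state k for annotation A is the percentage of
#' annotation bases falling in the state divided by the percentage of the
#' background universe falling in the state.
#'
#' @slot folds K x A matrix of fold enrichments (\code{NA} where undefined).
#' @slot genomeFraction per-state fraction of the universe.
#' @slot annotationFraction per-annotation fraction of the universe.
#' @export
setClass("EnrichmentTable",
  representation(folds = "matrix", genomeFraction = "numeric",
                 annotationFraction = "numeric"),
  validity = function(object) {
    msg <- NULL
    fv <- object@folds[!is.na(object@folds)]
    if (length(fv) && any(fv < 0)) msg <- c(msg, "folds must be non-negative")
    if (nrow(object@folds) != length(object@genomeFraction))
      msg <- c(msg, "one genomeFraction entry per state required")
    if (ncol(object@folds) != length(object@annotationFraction))
      msg <- c(msg, "one annotationFraction entry per annotation required")
    if (is.null(msg)) TRUE else msg
  })

#' Precision-recall curve
#'
#' Ordered cumulative precision/recall points, each contributed by one unit
#' (a state, a score bin, or an element set).
#'
#' @slot points data.frame with columns \code{unit}, \code{precision},
#'   \code{recall}; recall is non-decreasing along the curve.
#' @export
setClass("PRCurve",
  representation(points = "data.frame"),
  validity = function(object) {
    msg <- NULL
    need <- c("unit", "precision", "recall")
    if (!all(need %in% names(object@points)))
      msg <- c(msg, "points must have columns unit, precision, recall")
    else {
      p <- object@points$precision; r <- object@points$recall
      if (any(stats::na.omit(c(p, r)) < -1e-12) ||
          any(stats::na.omit(c(p, r)) > 1 + 1e-12))
        msg <- c(msg, "precision and recall must lie in [0,1]")
      if (is.unsorted(r, na.rm = TRUE))
        msg <- c(msg, "recall must be non-decreasing")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Hierarchical clustering of states with optimal leaf order
#'
#' @slot tree the \code{hclust} object (1 - Pearson correlation distance).
#' @slot leafOrder permutation of 1..K minimizing the summed distance
#'   between adjacent leaves among all orders consistent with the tree.
#' @slot groups integer group label per state from cutting the tree.
#' @slot K number of states.
#' @export
setClass("StateDendrogram",
  representation(tree = "ANY", leafOrder = "integer", groups = "integer",
                 K = "integer"),
  validity = function(object) {
    msg <- NULL
    if (!identical(sort(object@leafOrder), seq_len(object@K)))
      msg <- c(msg, "leafOrder must be a permutation of 1..K")
    if (length(object@groups) != object@K)
      msg <- c(msg, "one group label per state required")
    if (is.null(msg)) TRUE else msg
  })

#' Synthetic alignment dataset with known ground truth
#'
#' Holds the generative model, the true per-slice state paths, the
#' observation matrices emitted from them, and the seed, so every pipeline
#' stage can be checked against truth.
#'
#' @slot model the generating [ConsModel-class].
#' @slot partition the [GenomePartition-class] simulated over.
#' @slot paths list of [StatePath-class], one per slice.
#' @slot obs list of [ObservationMatrix-class], one per slice.
#' @slot seed integer seed used.
#' @export
setClass("SyntheticTruth",
  representation(model = "ConsModel", partition = "GenomePartition",
                 paths = "list", obs = "list", seed = "integer"),
  validity = function(object) {
    if (length(object@paths) != length(object@obs))
      "paths and obs must have one entry per slice" else TRUE
  })
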