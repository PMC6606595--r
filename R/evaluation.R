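## Precision-recall recovery of target annotations by states, raw scores,
## 400-bin score partitions and element sets, plus top-percent score set
## construction. Score tracks are GRanges with a numeric 'score' column
## over the bases where the score is defined; uncovered bases are
## undefined.

#' Read a per-base score track
#'
#' 4-column TSV (chrom, start, end, value) with 0-based half-open
#' intervals of constant score. Bases covered by no interval are treated
#' as score-undefined.
#'
#' @param file path (gzip supported).
#' @return \code{GRanges} with a numeric \code{score} column.
#' @export
readScoreTrack <- function(file) {
  con <- .open_text(file)
  on.exit(close(con))
  d <- read.table(con, sep = "\t", header = FALSE,
                  col.names = c("chrom", "start", "end", "score"),
                  colClasses = c("character", "numeric", "numeric", "numeric"))
  GRanges(d$chrom, IRanges(d$start + 1L, d$end), score = d$score)
}

#' Random half split of the genome slices
#'
#' Splits the slices of a partition into disjoint train and test halves
#' (sizes differing by at most one) with the seeded RNG; the same seed
#' reproduces the same split.
#'
#' @param partition a [GenomePartition-class].
#' @param seed integer seed.
#' @return List with \code{train} and \code{test} \code{GRanges} of slices.
#' @export
splitTrainTest <- function(partition, seed = 1L) {
  rs <- .seed_guard(seed)
  on.exit(rs())
  n <- length(partition@slices)
  perm <- sample.int(n)
  nTrain <- ceiling(n / 2)
  list(train = GenomicRanges::sort(partition@slices[perm[seq_len(nTrain)]]),
       test = GenomicRanges::sort(partition@slices[perm[-seq_len(nTrain)]]))
}

## cumulative PR curve from per-unit test-set sizes and true positives
.pr_from_counts <- function(units, sizes, tps, targetTest) {
  cs <- cumsum(sizes)
  ct <- cumsum(tps)
  new("PRCurve", points = data.frame(
    unit = units,
    precision = ifelse(cs > 0, ct / cs, NA_real_),
    recall = if (targetTest > 0) ct / targetTest else NA_real_))
}

#' Precision-recall recovery of a target annotation by states
#'
#' States are ordered by decreasing fold enrichment for the target among
#' the training-half bases (ties broken by state index); test-half bases
#' are then added state by state to form cumulative predicted sets, and
#' precision/recall of each cumulative set for the target is computed on
#' the test half only.
#'
#' @param seg a [Segmentation-class].
#' @param target \code{GRanges} target annotation (nonempty on both halves).
#' @param train,test slice \code{GRanges} from [splitTrainTest()].
#' @return A [PRCurve-class] with one point per state.
#' @export
prByStates <- function(seg, target, train, test) {
  target <- reduce(target)
  trainU <- reduce(train)
  testU <- reduce(test)
  et <- suppressWarnings(overlapEnrichment(seg, target, universe = trainU))
  fold <- et@folds[, 1L]
  ord <- order(is.na(fold), -ifelse(is.na(fold), 0, fold), seq_along(fold))
  stateR <- .state_ranges(seg)
  targetTestGR <- GenomicRanges::intersect(target, testU)
  sizes <- vapply(stateR[ord], function(s)
    .bases(GenomicRanges::intersect(s, testU)), numeric(1))
  tps <- vapply(stateR[ord], function(s)
    .bases(GenomicRanges::intersect(s, targetTestGR)), numeric(1))
  .pr_from_counts(paste0("state", ord), sizes, tps, .bases(targetTestGR))
}

## per-base expansion of a (small) GRanges extent
.expand_positions <- function(gr) {
  gr <- reduce(gr)
  list(chrom = rep(as.character(seqnames(gr)), width(gr)),
       pos = unlist(lapply(seq_along(gr), function(i)
         seq.int(start(gr)[i], end(gr)[i]))))
}

## score value at each position (NA where undefined)
.values_at <- function(score, chrom, pos) {
  q <- GRanges(chrom, IRanges(pos, pos))
  hit <- findOverlaps(q, score)
  v <- rep(NA_real_, length(q))
  v[queryHits(hit)] <- mcols(score)$score[subjectHits(hit)]
  v
}

#' Partition a score track into equal-occupancy bins
#'
#' Assigns every base of the universe a bin label: score-undefined bases
#' form one bin, and the score-defined bases are divided as evenly as
#' possible (within one base) among the remaining \code{nBins - 1} bins in
#' descending score order. A run of equal scores (a score increment)
#' straddling a bin boundary is split across those bins proportionally, the
#' individual bases being allocated uniformly at random with the seeded
#' RNG.
#'
#' @param score \code{GRanges} score track.
#' @param universe \code{GRanges} extent to bin (every base gets a label).
#' @param nBins total number of bins including the undefined bin
#'   (default 400).
#' @param seed integer seed for the proportional tie splitting.
#' @return A [Segmentation-class] over the universe with K = \code{nBins}
#'   states: state 1 is the score-undefined bin and states 2..nBins follow
#'   descending score order.
#' @export
binScore <- function(score, universe, nBins = 400L, seed = 1L) {
  if (nBins < 2L) stop("nBins must be at least 2")
  rs <- .seed_guard(seed)
  on.exit(rs())
  px <- .expand_positions(universe)
  v <- .values_at(score, px$chrom, px$pos)
  lab <- rep(1L, length(v))
  defIdx <- which(!is.na(v))
  nd <- length(defIdx)
  if (nd > 0) {
    nb <- nBins - 1L
    quota <- rep(nd %/% nb, nb)
    extra <- nd %% nb
    if (extra > 0) quota[seq_len(extra)] <- quota[seq_len(extra)] + 1L
    ## descending score; bases within an equal-score increment in random
    ## order, so increments straddling boundaries split proportionally
    ord <- defIdx[order(-v[defIdx], sample.int(nd))]
    lab[ord] <- rep(seq_len(nb) + 1L, quota)[seq_len(nd)]
  }
  labs <- split(lab, px$chrom)
  ## preserve genomic order within chromosome
  posL <- split(px$pos, px$chrom)
  labs <- lapply(names(labs), function(ch) labs[[ch]][order(posL[[ch]])])
  names(labs) <- names(posL)
  segmentationFromLabels(labs, K = nBins)
}

#' @describeIn prByStates the same procedure with score bins (from
#'   [binScore()]) treated as states.
#' @param binned binned score [Segmentation-class] from [binScore()].
#' @export
prByBins <- function(binned, target, train, test) {
  prByStates(binned, target, train, test)
}

#' Precision-recall by thresholding a raw score
#'
#' Orders test-half bases in descending score order (undefined bases
#' last) and computes precision/recall of the cumulative sets at every
#' distinct score threshold.
#'
#' @param score \code{GRanges} score track.
#' @param target \code{GRanges} target annotation.
#' @param test slice \code{GRanges} (the evaluation half).
#' @return A [PRCurve-class] with one point per distinct score value plus
#'   one for the undefined remainder (if any).
#' @export
prByRawScore <- function(score, target, test) {
  testU <- reduce(test)
  px <- .expand_positions(testU)
  v <- .values_at(score, px$chrom, px$pos)
  targetTestGR <- GenomicRanges::intersect(reduce(target), testU)
  inT <- rep(FALSE, length(v))
  if (length(targetTestGR)) {
    hit <- findOverlaps(GRanges(px$chrom, IRanges(px$pos, px$pos)),
                        targetTestGR)
    inT[queryHits(hit)] <- TRUE
  }
  vals <- sort(unique(v[!is.na(v)]), decreasing = TRUE)
  sizes <- tps <- numeric(0)
  units <- character(0)
  for (val in vals) {
    sel <- !is.na(v) & v == val
    sizes <- c(sizes, sum(sel))
    tps <- c(tps, sum(inT[sel]))
    units <- c(units, paste0("score>=", val))
  }
  if (anyNA(v)) {
    sizes <- c(sizes, sum(is.na(v)))
    tps <- c(tps, sum(inT[is.na(v)]))
    units <- c(units, "undefined")
  }
  .pr_from_counts(units, sizes, tps, sum(inT))
}

#' Single precision-recall point of an element set
#'
#' Precision and recall of the bases of an element set (e.g. a constrained
#' element call set) for the target, on the test half.
#'
#' @param elements \code{GRanges} element set.
#' @param target \code{GRanges} target annotation.
#' @param test slice \code{GRanges}.
#' @return A [PRCurve-class] with a single point.
#' @export
prPointElements <- function(elements, target, test) {
  testU <- reduce(test)
  el <- GenomicRanges::intersect(reduce(elements), testU)
  tg <- GenomicRanges::intersect(reduce(target), testU)
  tp <- .bases(GenomicRanges::intersect(el, tg))
  .pr_from_counts("elements", .bases(el), tp, .bases(tg))
}

## rename seqnames chrom -> chrom#sample
.concat_seqnames <- function(gr, sample) {
  out <- GRanges(paste0(as.character(seqnames(gr)), "#", sample),
                 IRanges(start(gr), end(gr)), strand = strand(gr))
  mcols(out) <- mcols(gr)
  out
}

#' Concatenate per-sample annotations onto a pseudo-genome
#'
#' Combines one target annotation per sample (e.g. DHS calls from many
#' cell types) into a single annotation on a concatenated pseudo-genome in
#' which every chromosome/sample combination becomes a new chromosome
#' named \code{chrom#sample}. Use [replicateAcrossSamples()] to place a
#' segmentation or score track onto the same pseudo-genome; downstream PR
#' operations then work unchanged, each state's size effectively
#' multiplied by the number of samples.
#'
#' @param targets named list of \code{GRanges}, one per sample.
#' @return \code{GRanges} on the pseudo-genome.
#' @export
concatTargets <- function(targets) {
  if (is.null(names(targets)) || !all(nzchar(names(targets))))
    stop("targets must be a named list (one name per sample)")
  suppressWarnings(do.call(c, lapply(names(targets), function(s)
    .concat_seqnames(targets[[s]], s))))
}

#' @rdname concatTargets
#' @param x a \code{GRanges} or [Segmentation-class] to replicate.
#' @param samples character vector of sample names.
#' @export
replicateAcrossSamples <- function(x, samples) {
  if (is(x, "Segmentation")) {
    runs <- suppressWarnings(do.call(c, lapply(samples, function(s)
      .concat_seqnames(x@runs, s))))
    return(Segmentation(runs, K = x@K))
  }
  suppressWarnings(do.call(c, lapply(samples, function(s)
    .concat_seqnames(x, s))))
}

#' Top-fraction base set of a score
#'
#' Chooses the score threshold (over distinct score values) whose top set
#' size is closest to \code{fraction} of the universe, preferring the
#' smaller set on ties. Score-undefined bases rank below every defined
#' value but still count toward the universe size used for the percentage.
#'
#' @param score \code{GRanges} score track.
#' @param fraction target fraction in (0, 1), e.g. 0.01, 0.05, 0.10.
#' @param universe \code{GRanges} of all bases considered.
#' @return \code{GRanges} of the selected bases (merged intervals).
#' @export
topFractionSet <- function(score, fraction, universe) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  px <- .expand_positions(universe)
  v <- .values_at(score, px$chrom, px$pos)
  vals <- sort(unique(v[!is.na(v)]), decreasing = TRUE)
  sizes <- cumsum(vapply(vals, function(val)
    sum(!is.na(v) & v == val), numeric(1)))
  ## candidates: empty set, each distinct-value cut, the whole universe
  candSizes <- c(0, sizes, length(v))
  targetN <- fraction * length(v)
  dist <- abs(candSizes - targetN)
  best <- which(dist == min(dist))[1L]  # ties -> smaller set (first index)
  if (best == 1L) return(GRanges())
  sel <- if (best == length(candSizes)) rep(TRUE, length(v))
         else !is.na(v) & v >= vals[best - 1L]
  reduce(GRanges(px$chrom[sel], IRanges(px$pos[sel], px$pos[sel])))
}
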