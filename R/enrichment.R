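## Base-resolution fold enrichment of states for interval annotations:
## overlap, background-restricted, positional (neighborhood), and the
## promoter-proximal gene ranking. Annotations are plain GRanges; a base
## counts once (intervals are merged before counting).

#' Read a BED annotation as GRanges
#'
#' BED3/BED6; strand is read from column 6 when present. Thin wrapper over
#' \code{rtracklayer::import}.
#'
#' @param file BED path (gzip supported).
#' @return \code{GRanges}.
#' @export
readAnnotationBED <- function(file) {
  rtracklayer::import(file, format = "BED")
}

.state_ranges <- function(seg) {
  lapply(seq_len(seg@K), function(k)
    reduce(seg@runs[mcols(seg@runs)$state == k]))
}

.bases <- function(gr) sum(as.numeric(width(gr)))

#' Per-state base fractions of a segmentation
#'
#' @param seg a [Segmentation-class].
#' @param universe optional \code{GRanges} restricting the background;
#'   defaults to the whole segmented extent.
#' @return Numeric vector of length K summing to 1 over annotated bases.
#' @export
stateFractions <- function(seg, universe = NULL) {
  if (is.null(universe)) universe <- reduce(seg@runs)
  else universe <- reduce(universe)
  tot <- .bases(universe)
  vapply(.state_ranges(seg), function(s)
    .bases(GenomicRanges::intersect(s, universe)) / tot, numeric(1))
}

#' Fold enrichment of states for external annotations
#'
#' For each state, the percentage of annotation bases falling in the state
#' divided by the percentage of the background universe falling in the
#' state (a uniform background). The universe defaults to the whole
#' segmented genome; supplying a restricted universe (e.g. non-coding
#' bases, a motif-calling background) computes background-restricted
#' enrichments. Annotation bases outside the universe are clipped with a
#' warning. An empty annotation yields a column of \code{NA}.
#'
#' @param seg a [Segmentation-class].
#' @param ann a \code{GRanges} annotation, or a named list of them.
#' @param universe optional background \code{GRanges}.
#' @return An [EnrichmentTable-class] with one column per annotation.
#' @examples
#' seg <- segmentationFromLabels(list(chr1 = rep(c(1, 2), c(20, 80))))
#' ann <- GenomicRanges::GRanges("chr1", IRanges::IRanges(16, 25))
#' folds(overlapEnrichment(seg, ann))  # state1: (5/10)/(20/100) = 2.5
#' @export
overlapEnrichment <- function(seg, ann, universe = NULL) {
  if (!is.list(ann)) ann <- stats::setNames(list(ann), "annotation")
  if (is.null(names(ann))) names(ann) <- paste0("ann", seq_along(ann))
  if (is.null(universe)) universe <- reduce(seg@runs)
  else universe <- reduce(universe)
  uniBases <- .bases(universe)
  stateR <- lapply(.state_ranges(seg), GenomicRanges::intersect, universe)
  stateBases <- vapply(stateR, .bases, numeric(1))
  gf <- stateBases / uniBases
  foldM <- matrix(NA_real_, seg@K, length(ann),
                  dimnames = list(paste0("state", seq_len(seg@K)), names(ann)))
  af <- setNames(numeric(length(ann)), names(ann))
  for (i in seq_along(ann)) {
    a <- reduce(ann[[i]])
    aClip <- GenomicRanges::intersect(a, universe)
    if (.bases(aClip) < .bases(a))
      warning("annotation '", names(ann)[i], "': ",
              .bases(a) - .bases(aClip), " base(s) outside universe clipped")
    nA <- .bases(aClip)
    af[i] <- nA / uniBases
    if (nA == 0) next
    inState <- vapply(stateR, function(s)
      .bases(GenomicRanges::intersect(s, aClip)), numeric(1))
    foldM[, i] <- ifelse(gf > 0, (inState / nA) / gf, NA_real_)
  }
  new("EnrichmentTable", folds = foldM, genomeFraction = gf,
      annotationFraction = af)
}

#' Enrichment of a foreground relative to a background region
#'
#' Elementwise ratio of fold enrichments, e.g. the enrichment of a top-
#' score set within non-coding regions divided by the enrichment of the
#' non-coding background itself. A zero background fold gives \code{NA}.
#'
#' @param foldForeground,foldBackground numeric vectors (or single-column
#'   [EnrichmentTable-class] folds) of per-state enrichments.
#' @return Numeric vector of ratios.
#' @export
relativeEnrichment <- function(foldForeground, foldBackground) {
  fg <- if (is(foldForeground, "EnrichmentTable"))
    foldForeground@folds[, 1L] else foldForeground
  bg <- if (is(foldBackground, "EnrichmentTable"))
    foldBackground@folds[, 1L] else foldBackground
  ifelse(!is.na(bg) & bg != 0, fg / bg, NA_real_)
}

#' Positional state enrichment around anchor points
#'
#' For each signed offset d in [-left, right] (single-base spacing), the
#' fraction of anchors whose base at offset d lies in state k, divided by
#' the genome fraction of state k. Negative-strand anchors have offsets
#' mirrored, so positive offsets are downstream in the 5' to 3' direction.
#' Offsets falling outside the segmented extent are skipped per anchor; the
#' denominator at each offset is the number of anchors contributing there.
#'
#' @param seg a [Segmentation-class].
#' @param anchors \code{GRanges} of anchor positions (width-1; for wider
#'   ranges the 5' base is used); strand read from the object.
#' @param left,right bases upstream / downstream of the anchor.
#' @return (left+right+1) x K matrix of fold enrichments, rownames the
#'   offsets.
#' @export
neighborhoodEnrichment <- function(seg, anchors, left, right) {
  if (!length(anchors)) stop("zero anchors supplied")
  str <- as.character(strand(anchors))
  pos <- ifelse(str == "-", end(anchors), start(anchors))
  chrom <- as.character(seqnames(anchors))
  neg <- str == "-"
  offs <- seq(-left, right)
  gf <- stateFractions(seg)
  ## state lookup for all anchor/offset positions in one overlap query
  n <- length(anchors)
  posAll <- rep(pos, each = length(offs)) +
    rep(ifelse(neg, -1, 1), each = length(offs)) * rep(offs, n)
  chromAll <- rep(chrom, each = length(offs))
  ok <- posAll >= 1
  q <- GRanges(chromAll[ok], IRanges(posAll[ok], posAll[ok]))
  hit <- findOverlaps(q, seg@runs)
  stAll <- rep(NA_integer_, length(posAll))
  idx <- which(ok)
  stAll[idx[queryHits(hit)]] <- mcols(seg@runs)$state[subjectHits(hit)]
  stM <- matrix(stAll, nrow = length(offs))  # offsets x anchors
  out <- matrix(NA_real_, length(offs), seg@K,
                dimnames = list(offs, paste0("state", seq_len(seg@K))))
  for (d in seq_along(offs)) {
    s <- stM[d, ]
    nC <- sum(!is.na(s))
    if (nC == 0) next
    cnt <- tabulate(s[!is.na(s)], nbins = seg@K)
    out[d, ] <- ifelse(gf > 0, (cnt / nC) / gf, NA_real_)
  }
  out
}

#' Rank genes by promoter-proximal bases in each state
#'
#' For each state and gene, counts the bases of that state within +/-
#' \code{window} of the gene's TSS (a symmetric closed window of
#' 2*window+1 bases including the TSS base), sorts genes by descending
#' count (ties broken by gene identifier), and takes the top fraction.
#' Callers with multiple TSS per gene should pre-select the outermost one.
#'
#' @param seg a [Segmentation-class].
#' @param tss width-1 \code{GRanges} of TSS with a \code{gene} metadata
#'   column (one row per gene).
#' @param window bases on each side of the TSS (default 2000).
#' @param topFraction fraction of genes in the top set (default 0.05);
#'   the top set size is \code{round(topFraction * #genes)}.
#' @return List with \code{counts} (genes x states base-count matrix),
#'   \code{ranking} (per-state character vector of gene ids, best first)
#'   and \code{topGenes} (per-state head of the ranking).
#' @export
rankGenesByState <- function(seg, tss, window = 2000L, topFraction = 0.05) {
  genes <- as.character(mcols(tss)$gene)
  if (is.null(genes) || anyDuplicated(genes))
    stop("tss must carry one 'gene' id per row, without duplicates")
  win <- GRanges(seqnames(tss),
                 IRanges(pmax(start(tss) - window, 1L), start(tss) + window))
  hit <- findOverlaps(win, seg@runs)
  ov <- width(GenomicRanges::pintersect(win[queryHits(hit)],
                                        seg@runs[subjectHits(hit)]))
  st <- mcols(seg@runs)$state[subjectHits(hit)]
  counts <- matrix(0L, length(genes), seg@K,
                   dimnames = list(genes, paste0("state", seq_len(seg@K))))
  if (length(hit)) {
    ag <- stats::aggregate(ov, list(gene = queryHits(hit), state = st), sum)
    counts[cbind(ag$gene, ag$state)] <- ag$x
  }
  nTop <- round(topFraction * length(genes))
  ranking <- lapply(seq_len(seg@K), function(k) {
    genes[order(-counts[, k], genes)]
  })
  names(ranking) <- colnames(counts)
  list(counts = counts, ranking = ranking,
       topGenes = lapply(ranking, head, nTop))
}
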