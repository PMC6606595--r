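## Posterior decoding, merging sliced decodings into a genome-wide
## segmentation, the uniform-transition comparison model, and segment
## accounting. GRanges follow the usual 1-based closed R convention; BED
## files on disk are 0-based half-open.

#' Decode a slice to per-base state labels
#'
#' Assigns each base the state with maximum posterior probability; ties are
#' broken toward the lowest state index. Implemented as a method on the
#' \code{S4Vectors::decode} generic.
#'
#' @param x a [ConsModel-class].
#' @param obs an [ObservationMatrix-class], or a precomputed
#'   [PosteriorMatrix-class].
#' @return A [StatePath-class].
#' @importFrom S4Vectors decode
#' @export decode
#' @exportMethod decode
#' @aliases decode
setMethod("decode", "ConsModel", function(x, obs) {
  post <- if (is(obs, "PosteriorMatrix")) obs else forwardBackward(x, obs)
  new("StatePath", chrom = post@chrom, chromStart = post@chromStart,
      chromEnd = post@chromEnd,
      states = max.col(post@values, ties.method = "first"),
      K = x@K)
})

## sort runs and merge adjacent contiguous runs with equal state
.normalize_runs <- function(gr) {
  gr <- GenomicRanges::sort(gr)
  if (length(gr) < 2L) return(gr)
  st <- mcols(gr)$state
  ch <- as.character(seqnames(gr))
  joins <- ch[-1L] == ch[-length(gr)] &
    start(gr)[-1L] == end(gr)[-length(gr)] + 1L &
    st[-1L] == st[-length(gr)]
  grp <- cumsum(c(TRUE, !joins))
  s <- tapply(start(gr), grp, min)
  e <- tapply(end(gr), grp, max)
  first <- !duplicated(grp)
  GRanges(ch[first], IRanges(as.integer(s), as.integer(e)),
          state = st[first])
}

#' Build a Segmentation from runs or per-base labels
#'
#' \code{Segmentation} normalizes the supplied run intervals (sorting and
#' merging touching runs of equal state) so the stored runs are maximal.
#' \code{segmentationFromLabels} converts per-base state label vectors
#' (one per chromosome) to their run-length interval representation.
#'
#' @param runs \code{GRanges} with an integer \code{state} metadata column.
#' @param K number of states (defaults to the maximum label present).
#' @return A [Segmentation-class].
#' @examples
#' segmentationFromLabels(list(chr1 = c(1, 1, 2, 2, 2, 1)), K = 2)
#' @export
Segmentation <- function(runs, K = max(mcols(runs)$state)) {
  new("Segmentation", runs = .normalize_runs(runs), K = as.integer(K))
}

#' @rdname Segmentation
#' @param labels named list of integer vectors of per-base states, one
#'   element per chromosome.
#' @export
segmentationFromLabels <- function(labels, K = max(unlist(labels))) {
  grs <- lapply(names(labels), function(ch) {
    r <- rle(as.integer(labels[[ch]]))
    e <- cumsum(r$lengths)
    GRanges(ch, IRanges(c(1L, head(e, -1L) + 1L), e), state = r$values)
  })
  ## seqlevels differ across chromosomes by construction; combining is safe
  runs <- suppressWarnings(do.call(c, grs))
  new("Segmentation", runs = runs, K = as.integer(K))
}

#' Per-base state labels of a segmentation over one interval
#'
#' @param seg a [Segmentation-class].
#' @param chrom chromosome name.
#' @param start,end 1-based closed interval (defaults to the chromosome's
#'   annotated extent).
#' @return Integer vector of states (\code{NA} where unannotated).
#' @export
stateLabels <- function(seg, chrom, start = NULL, end = NULL) {
  runs <- seg@runs[seqnames(seg@runs) == chrom]
  if (!length(runs)) stop("chromosome ", chrom, " not in segmentation")
  if (is.null(start)) start <- min(GenomicRanges::start(runs))
  if (is.null(end)) end <- max(GenomicRanges::end(runs))
  out <- rep(NA_integer_, end - start + 1L)
  for (i in seq_along(runs)) {
    lo <- max(GenomicRanges::start(runs)[i], start)
    hi <- min(GenomicRanges::end(runs)[i], end)
    if (lo <= hi) out[(lo - start + 1L):(hi - start + 1L)] <- mcols(runs)$state[i]
  }
  out
}

#' Merge per-slice state paths into a genome-wide segmentation
#'
#' Concatenates the per-slice decodings in genome order and merges runs of
#' equal state across slice boundaries, so the result is independent of
#' where slice boundaries fell. Every slice of the partition must be
#' supplied exactly once.
#'
#' @param paths list of [StatePath-class], one per slice.
#' @param partition the [GenomePartition-class] the slices came from.
#' @return A [Segmentation-class] tiling the partition's chromosomes.
#' @export
mergeSegmentation <- function(paths, partition) {
  sl <- partition@slices
  key <- paste0(as.character(seqnames(sl)), ":", start(sl) - 1L, "-", end(sl))
  pkey <- vapply(paths, function(p)
    paste0(p@chrom, ":", format(p@chromStart, scientific = FALSE, trim = TRUE),
           "-", format(p@chromEnd, scientific = FALSE, trim = TRUE)),
    character(1))
  miss <- setdiff(key, pkey)
  if (length(miss))
    stop("missing slice(s): ", paste(miss, collapse = ", "))
  dup <- pkey[duplicated(pkey)]
  if (length(dup))
    stop("duplicated slice(s): ", paste(unique(dup), collapse = ", "))
  ord <- match(key, pkey)
  K <- paths[[1L]]@K
  labels <- list()
  for (i in ord) {
    p <- paths[[i]]
    labels[[p@chrom]] <- c(labels[[p@chrom]], p@states)
  }
  segmentationFromLabels(labels, K = K)
}

#' Copy of a model with uniform transition probabilities
#'
#' Sets every transition probability to 1/K (e.g. 0.01 for a 100-state
#' model), so each state has equal probability of transitioning to any
#' state including itself; emissions and the initial distribution are
#' unchanged. Decoding under this model removes the smoothing effect of the
#' learned self-transitions, which typically increases the number of
#' segments.
#'
#' @param model a [ConsModel-class].
#' @param pUniform the uniform transition probability; must equal 1/K.
#' @return A [ConsModel-class].
#' @export
uniformTransitionModel <- function(model, pUniform = 1 / nStates(model)) {
  K <- model@K
  if (abs(pUniform * K - 1) > 1e-9)
    stop("pUniform must equal 1/K so transition rows sum to 1")
  ConsModel(model@species, a = model@a, b = matrix(1 / K, K, K),
            f = model@f, g = model@g)
}

#' Per-state agreement between two segmentations
#'
#' For each state, the fraction of bases assigned to it in \code{original}
#' that are also assigned to it in \code{other}. States absent from
#' \code{original} are reported as \code{NA}.
#'
#' @param original,other [Segmentation-class] objects over the same extent.
#' @return Named numeric vector of per-state fractions in [0,1].
#' @export
annotationAgreement <- function(original, other) {
  K <- max(original@K, other@K)
  out <- setNames(rep(NA_real_, K), paste0("state", seq_len(K)))
  for (k in seq_len(K)) {
    a <- reduce(original@runs[mcols(original@runs)$state == k])
    if (!length(a)) next
    b <- reduce(other@runs[mcols(other@runs)$state == k])
    both <- sum(width(GenomicRanges::intersect(a, b)))
    out[k] <- both / sum(width(a))
  }
  out
}

#' Number of maximal constant-state segments
#'
#' @param seg a [Segmentation-class].
#' @return Integer count of maximal runs.
#' @export
countSegments <- function(seg) {
  length(seg@runs)
}

#' Decode all slices and merge into a genome-wide segmentation
#'
#' @param model a [ConsModel-class].
#' @param obsList list of [ObservationMatrix-class], one per slice.
#' @param partition the matching [GenomePartition-class].
#' @return A [Segmentation-class].
#' @export
segmentGenome <- function(model, obsList, partition) {
  mergeSegmentation(lapply(obsList, function(o) decode(model, o)), partition)
}

#' Write / read a segmentation as BED4
#'
#' 0-based half-open intervals; the name field carries the 1-based state
#' label, optionally mapped through a mnemonic vector. Gzip output is
#' selected by a '.gz' suffix.
#'
#' @param seg a [Segmentation-class].
#' @param file path.
#' @param mnemonics optional character vector of length K mapping state
#'   labels to names.
#' @return \code{writeSegmentationBED}: the path invisibly;
#'   \code{readSegmentationBED}: a [Segmentation-class].
#' @export
writeSegmentationBED <- function(seg, file, mnemonics = NULL) {
  runs <- seg@runs
  nm <- mcols(runs)$state
  if (!is.null(mnemonics)) nm <- mnemonics[nm]
  con <- if (grepl("\\.gz$", file)) gzfile(file, "wt") else file(file, "wt")
  on.exit(close(con))
  writeLines(paste(as.character(seqnames(runs)), start(runs) - 1L, end(runs),
                   nm, sep = "\t"), con)
  invisible(file)
}

#' @rdname writeSegmentationBED
#' @param K number of states (defaults to the maximum label in the file).
#' @export
readSegmentationBED <- function(file, K = NULL) {
  con <- .open_text(file)
  on.exit(close(con))
  d <- read.table(con, sep = "\t", header = FALSE,
                  col.names = c("chrom", "start", "end", "state"),
                  colClasses = c("character", "numeric", "numeric", "integer"))
  gr <- GRanges(d$chrom, IRanges(d$start + 1L, d$end), state = d$state)
  Segmentation(gr, K = if (is.null(K)) max(d$state) else K)
}
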