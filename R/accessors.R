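#' @rdname SpeciesSet
#' @param object,x a ConsStates object.
#' @export
setGeneric("referenceGenome", function(object) standardGeneric("referenceGenome"))

#' @rdname SpeciesSet
#' @export
setGeneric("otherSpecies", function(object) standardGeneric("otherSpecies"))

#' @rdname ConsModel
#' @export
setGeneric("nStates", function(object) standardGeneric("nStates"))

#' @rdname ConsModel
#' @export
setGeneric("alignProb", function(object) standardGeneric("alignProb"))

#' @rdname ConsModel
#' @export
setGeneric("matchProb", function(object) standardGeneric("matchProb"))

#' @rdname ConsModel
#' @export
setGeneric("transitionMatrix", function(object) standardGeneric("transitionMatrix"))

#' @rdname ConsModel
#' @export
setGeneric("initialProb", function(object) standardGeneric("initialProb"))

#' @rdname Segmentation
#' @export
setGeneric("stateRuns", function(object) standardGeneric("stateRuns"))

#' @rdname PosteriorMatrix
#' @export
setGeneric("posteriors", function(object) standardGeneric("posteriors"))

#' @rdname EnrichmentTable
#' @export
setGeneric("folds", function(object) standardGeneric("folds"))

#' @rdname PRCurve
#' @export
setGeneric("prPoints", function(object) standardGeneric("prPoints"))

setMethod("referenceGenome", "SpeciesSet", function(object) object@reference)
setMethod("otherSpecies", "SpeciesSet", function(object) object@others)
setMethod("referenceGenome", "ConsModel", function(object) object@species@reference)
setMethod("otherSpecies", "ConsModel", function(object) object@species@others)
setMethod("nStates", "ConsModel", function(object) object@K)
setMethod("nStates", "Segmentation", function(object) object@K)
setMethod("alignProb", "ConsModel", function(object) object@f)
setMethod("matchProb", "ConsModel", function(object) object@g)
setMethod("transitionMatrix", "ConsModel", function(object) object@b)
setMethod("initialProb", "ConsModel", function(object) object@a)
setMethod("stateRuns", "Segmentation", function(object) object@runs)
setMethod("posteriors", "PosteriorMatrix", function(object) object@values)
setMethod("folds", "EnrichmentTable", function(object) object@folds)
setMethod("prPoints", "PRCurve", function(object) object@points)

#' @describeIn GenomePartition number of slices.
#' @param x a GenomePartition.
#' @export
setMethod("length", "GenomePartition", function(x) length(x@slices))

#' @describeIn GenomePartition the slice GRanges.
#' @export
setGeneric("slices", function(object) standardGeneric("slices"))
setMethod("slices", "GenomePartition", function(object) object@slices)

#' Derived three-way multinomial emission parameters
#'
#' Converts the two-Bernoulli (f, g) parameterization to the equivalent
#' per-state, per-species multinomial over the three observations:
#' p1 = f*g (align+match), p2 = f*(1-g) (align+mismatch), p3 = 1-f
#' (unaligned). The three probabilities sum to 1 exactly for every (k, j).
#'
#' @param object a [ConsModel-class].
#' @return K x (N-1) x 3 array.
#' @export
setGeneric("emissionMultinomial", function(object) standardGeneric("emissionMultinomial"))
setMethod("emissionMultinomial", "ConsModel", function(object) {
  p <- array(0, dim = c(object@K, ncol(object@f), 3L),
             dimnames = list(NULL, object@species@others,
                             c("alignMatch", "alignMismatch", "unaligned")))
  p[, , 1L] <- object@f * object@g
  p[, , 2L] <- object@f * (1 - object@g)
  ## complement of the first two terms: the three probabilities then sum
  ## to 1 exactly in floating point (1 - f would not guarantee that)
  p[, , 3L] <- 1 - (p[, , 1L] + p[, , 2L])
  p
})

setMethod("show", "SpeciesSet", function(object) {
  cat("SpeciesSet: reference", object@reference, "+",
      length(object@others), "species\n")
  cat("  ", paste(head(object@others, 8), collapse = ", "),
      if (length(object@others) > 8) ", ..." else "", "\n", sep = "")
})

setMethod("show", "GenomePartition", function(object) {
  cat("GenomePartition:", length(object@chromLengths), "chromosome(s),",
      length(object@slices), "slice(s) of", object@sliceLength, "b\n")
})

setMethod("show", "ObservationMatrix", function(object) {
  cat(sprintf("ObservationMatrix: %s:%d-%d (%d b x %d species)\n",
              object@chrom, object@chromStart, object@chromEnd,
              nrow(object@y), ncol(object@y)))
  al <- mean(object@y)
  cat(sprintf("  aligned fraction %.3f; match fraction (given aligned) %.3f\n",
              al, if (al > 0) mean(object@z, na.rm = TRUE) else NA_real_))
})

setMethod("show", "ConsModel", function(object) {
  cat(sprintf("ConsModel: %d states over %d species (reference %s)\n",
              object@K, ncol(object@f), object@species@reference))
  if (length(object@fitInfo))
    cat(sprintf("  trained: %d iterations, final loglik %.4f\n",
                length(object@fitInfo$loglik),
                tail(object@fitInfo$loglik, 1)))
})

setMethod("show", "Segmentation", function(object) {
  cat(sprintf("Segmentation: %d run(s), %d state(s), %.0f bases over %d chromosome(s)\n",
              length(object@runs), object@K, sum(width(object@runs)),
              length(unique(as.character(seqnames(object@runs))))))
})

setMethod("show", "EnrichmentTable", function(object) {
  cat(sprintf("EnrichmentTable: %d state(s) x %d annotation(s)\n",
              nrow(object@folds), ncol(object@folds)))
  print(round(head(object@folds, 10), 3))
})

setMethod("show", "PRCurve", function(object) {
  cat(sprintf("PRCurve: %d point(s); final recall %.3f\n",
              nrow(object@points),
              if (nrow(object@points)) tail(object@points$recall, 1) else NA))
})

setMethod("show", "StateDendrogram", function(object) {
  cat(sprintf("StateDendrogram: %d state(s), %d group(s); leaf order: %s\n",
              object@K, length(unique(object@groups)),
              paste(object@leafOrder, collapse = " ")))
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth: %d slice(s), %d-state model, seed %d\n",
              length(object@obs), object@model@K, object@seed))
})
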