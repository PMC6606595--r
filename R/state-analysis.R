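## State clustering and diagnostics: correlation clustering of the
## [f, f*g] state feature vectors with exact optimal leaf ordering, the
## normalized enrichment-matrix clustering, and per-state posterior
## confidence.

#' Per-state feature vectors for clustering
#'
#' Concatenates, for each state, the per-species align probabilities f and
#' the joint align-and-match probabilities f*g into a vector of length
#' 2(N-1). States are clustered on the Pearson correlation of these
#' vectors.
#'
#' @param model a [ConsModel-class].
#' @return K x 2(N-1) matrix.
#' @export
stateFeatureVectors <- function(model) {
  v <- cbind(model@f, model@f * model@g)
  colnames(v) <- c(paste0(model@species@others, "_align"),
                   paste0(model@species@others, "_alignMatch"))
  v
}

## Exact optimal leaf ordering (dynamic program over the dendrogram):
## among all 2^(K-1) leaf orders consistent with the tree, find one
## minimizing the summed distance between adjacent leaves. M[l, r] is the
## minimal cost of ordering a subtree's leaves with l leftmost and r
## rightmost; merging children A and B combines MA and MB through the
## cross-distance of their facing leaves.
.olo <- function(hc, d) {
  K <- nrow(d)
  nodes <- vector("list", nrow(hc$merge))
  leafNode <- function(i) list(leaves = i,
                               M = matrix(0, 1, 1, dimnames = list(i, i)))
  getNode <- function(id) if (id < 0) leafNode(-id) else nodes[[id]]
  for (n in seq_len(nrow(hc$merge))) {
    A <- getNode(hc$merge[n, 1L])
    B <- getNode(hc$merge[n, 2L])
    LA <- A$leaves; LB <- B$leaves
    ## minA[l, w] = min_u MA[l, u] + d[u, w]  (u in LA, w in LB)
    minA <- matrix(Inf, length(LA), length(LB), dimnames = list(LA, LB))
    for (li in seq_along(LA))
      minA[li, ] <- apply(A$M[li, , drop = FALSE][1, ] + d[LA, LB, drop = FALSE],
                          2, min)
    M <- matrix(Inf, length(LA) + length(LB), length(LA) + length(LB),
                dimnames = list(c(LA, LB), c(LA, LB)))
    for (li in seq_along(LA)) for (ri in seq_along(LB)) {
      cost <- min(minA[li, ] + B$M[, ri])
      M[li, length(LA) + ri] <- cost
      M[length(LA) + ri, li] <- cost  # reversal has equal cost
    }
    nodes[[n]] <- list(leaves = c(LA, LB), M = M, A = A, B = B)
  }
  root <- nodes[[nrow(hc$merge)]]
  idx <- which(root$M == min(root$M), arr.ind = TRUE)[1L, ]
  l <- root$leaves[idx[1L]]
  r <- root$leaves[idx[2L]]
  recover <- function(node, l, r) {
    if (length(node$leaves) == 1L) return(node$leaves)
    A <- node$A; B <- node$B
    if (!(l %in% A$leaves)) { tmp <- A; A <- B; B <- tmp }  # put l's child left
    LA <- A$leaves; LB <- B$leaves
    best <- Inf; bu <- NA; bw <- NA
    for (u in LA) for (w in LB) {
      cost <- A$M[match(l, LA), match(u, LA)] + d[u, w] +
        B$M[match(w, LB), match(r, LB)]
      if (cost < best - 1e-12) { best <- cost; bu <- u; bw <- w }
    }
    c(recover(A, l, bu), recover(B, bw, r))
  }
  recover(root, l, r)
}

#' Hierarchically cluster states with optimal leaf ordering
#'
#' Agglomerative clustering of the state feature vectors with distance
#' 1 - Pearson correlation and complete linkage. The dendrogram's leaves
#' are then reordered by the exact optimal leaf ordering dynamic program
#' (minimal summed distance between adjacent leaves among all orders
#' consistent with the tree), and the tree is cut into \code{nGroups}
#' major state groups.
#'
#' @param vectors K x p matrix of state feature vectors (rows are states),
#'   e.g. from [stateFeatureVectors()]; or a [ConsModel-class].
#' @param nGroups number of groups to cut the tree into (default 8).
#' @param linkage linkage method passed to \code{hclust}
#'   (default "complete").
#' @return A [StateDendrogram-class].
#' @export
clusterStates <- function(vectors, nGroups = 8L, linkage = "complete") {
  if (is(vectors, "ConsModel")) vectors <- stateFeatureVectors(vectors)
  K <- nrow(vectors)
  if (K < 2L) stop("at least 2 states are required for clustering")
  sds <- apply(vectors, 1L, sd)
  if (any(sds == 0))
    stop("constant feature vector (zero variance) for state(s) ",
         paste(which(sds == 0), collapse = ", "),
         ": correlation undefined")
  d <- 1 - cor(t(vectors))
  hc <- hclust(as.dist(d), method = linkage)
  ord <- .olo(hc, d)
  nGroups <- min(nGroups, K)
  grp <- cutree(hc, k = nGroups)
  new("StateDendrogram", tree = hc, leafOrder = as.integer(ord),
      groups = as.integer(grp), K = as.integer(K))
}

#' Summed adjacent-leaf distance of a leaf order
#'
#' The objective minimized by the optimal leaf ordering: the sum of
#' distances between consecutive leaves.
#'
#' @param order integer permutation of 1..K.
#' @param d K x K distance matrix.
#' @return Numeric scalar.
#' @export
leafOrderCost <- function(order, d) {
  sum(d[cbind(order[-length(order)], order[-1L])])
}

#' Normalize and cluster a state x sample enrichment matrix
#'
#' Keeps states with a fold enrichment of at least \code{minFold} in at
#' least one sample, log2-transforms the folds (flooring folds at
#' \code{logFloor} so zeros stay finite), z-normalizes each state's row
#' (subtract the mean across samples, divide by the standard deviation),
#' and hierarchically clusters states and samples by their correlation
#' distance.
#'
#' @param enrich an [EnrichmentTable-class] or a K x S fold matrix.
#' @param minFold state retention threshold (default 2).
#' @param logFloor fold floor before log2 (default 0.01).
#' @return List with \code{matrix} (the z-normalized retained rows),
#'   \code{states} (retained state indices), \code{rowTree} and
#'   \code{colTree} (\code{hclust} objects).
#' @export
clusterEnrichmentMatrix <- function(enrich, minFold = 2.0, logFloor = 0.01) {
  m <- if (is(enrich, "EnrichmentTable")) enrich@folds else as.matrix(enrich)
  if (ncol(m) < 2L)
    stop("at least two samples are required: row z-scores are undefined ",
         "for a single column")
  keep <- which(apply(m, 1L, function(r) any(!is.na(r) & r >= minFold)))
  if (length(keep) < 2L)
    stop("fewer than two states reach minFold = ", minFold)
  lm <- log2(pmax(m[keep, , drop = FALSE], logFloor))
  sds <- apply(lm, 1L, sd)
  if (any(sds == 0))
    stop("state(s) ", paste(keep[sds == 0], collapse = ", "),
         " have constant enrichment across samples; z-score undefined")
  z <- (lm - rowMeans(lm)) / sds
  rowTree <- hclust(as.dist(1 - cor(t(z))), method = "complete")
  colTree <- hclust(as.dist(1 - cor(z)), method = "complete")
  list(matrix = z, states = keep, rowTree = rowTree, colTree = colTree)
}

#' Per-state mean assigned posterior probability
#'
#' For each state, the average posterior probability of that state over
#' the bases assigned to it — the model's internal confidence in its
#' assignments. States never assigned are \code{NA}.
#'
#' @param posteriors a [PosteriorMatrix-class] or list of them.
#' @param paths the matching [StatePath-class] (or list), e.g. from
#'   [decode()].
#' @return Named numeric vector of length K.
#' @export
posteriorConfidence <- function(posteriors, paths) {
  if (is(posteriors, "PosteriorMatrix")) posteriors <- list(posteriors)
  if (is(paths, "StatePath")) paths <- list(paths)
  stopifnot(length(posteriors) == length(paths))
  K <- ncol(posteriors[[1L]]@values)
  num <- den <- numeric(K)
  for (i in seq_along(posteriors)) {
    gam <- posteriors[[i]]@values
    st <- paths[[i]]@states
    p <- gam[cbind(seq_along(st), st)]
    num <- num + vapply(seq_len(K), function(k) sum(p[st == k]), numeric(1))
    den <- den + tabulate(st, nbins = K)
  }
  setNames(ifelse(den > 0, num / den, NA_real_),
           paste0("state", seq_len(K)))
}
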