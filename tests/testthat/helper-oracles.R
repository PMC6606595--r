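# Independent oracles: brute-force path enumeration for the HMM,
# per-base counting for enrichments and precision-recall, and exhaustive
# search over tree-consistent leaf orders.

# Sum over all K^T hidden paths; exact likelihood and posteriors.
bruteForceHMM <- function(model, obs) {
  K <- model@K
  Tn <- nrow(obs@y)
  emis <- sapply(seq_len(K), function(k)
    sapply(seq_len(Tn), function(t)
      emissionProb(model, k, obs@y[t, ], obs@z[t, ])))
  emis <- matrix(emis, Tn, K)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  w <- apply(paths, 1L, function(s) {
    p <- model@a[s[1L]] * prod(emis[cbind(seq_len(Tn), s)])
    if (Tn > 1L) p <- p * prod(model@b[cbind(s[-Tn], s[-1L])])
    p
  })
  lik <- sum(w)
  gamma <- matrix(0, Tn, K)
  for (t in seq_len(Tn)) for (k in seq_len(K))
    gamma[t, k] <- sum(w[paths[, t] == k]) / lik
  list(loglik = log(lik), gamma = gamma)
}

# per-base fold enrichment oracle on label/indicator vectors (one
# chromosome): labels[i] = state of base i, annMask[i] = TRUE if base in
# annotation, uniMask = universe membership
countingEnrichment <- function(labels, annMask, uniMask = NULL) {
  if (is.null(uniMask)) uniMask <- rep(TRUE, length(labels))
  K <- max(labels)
  ann <- annMask & uniMask
  vapply(seq_len(K), function(k) {
    inState <- labels == k & uniMask
    gf <- sum(inState) / sum(uniMask)
    if (gf == 0 || sum(ann) == 0) return(NA_real_)
    (sum(inState & ann) / sum(ann)) / gf
  }, numeric(1))
}

# all leaf orders consistent with an hclust tree (flipping children at
# every internal node), as a matrix of orders
allTreeOrders <- function(hc) {
  rec <- function(id) {
    if (id < 0) return(list(-id))
    A <- rec(hc$merge[id, 1L])
    B <- rec(hc$merge[id, 2L])
    out <- list()
    for (x in A) for (y in B) {
      out[[length(out) + 1L]] <- c(x, y)
      out[[length(out) + 1L]] <- c(y, x)
    }
    out
  }
  do.call(rbind, rec(nrow(hc$merge)))
}
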