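## Synthetic alignments from a known generative model: ground-truth state
## paths, observation matrices, and MAF text, so every pipeline stage can
## be validated end to end without external data.

#' Simulate observations from a conservation-state model
#'
#' Samples, per slice of the partition, a hidden state path from the
#' initial and transition distributions (each slice is an independent
#' sequence), then per species an align indicator from f[state, species]
#' and, where aligned, a match indicator from g[state, species].
#' Reproducible given the seed.
#'
#' @param model the generating [ConsModel-class].
#' @param partition a [GenomePartition-class].
#' @param seed integer seed.
#' @return A [SyntheticTruth-class] holding the true paths and the
#'   emitted observation matrices.
#' @export
simulateAlignment <- function(model, partition, seed = 1L) {
  rs <- .seed_guard(seed)
  on.exit(rs())
  K <- model@K
  nsp <- length(model@species@others)
  cb <- matrix(0, K, K)
  for (k in seq_len(K)) cb[k, ] <- cumsum(model@b[k, ])
  ca <- cumsum(model@a)
  sl <- partition@slices
  paths <- obs <- vector("list", length(sl))
  for (i in seq_along(sl)) {
    Tn <- width(sl)[i]
    u <- runif(Tn)
    s <- integer(Tn)
    s[1L] <- findInterval(u[1L], ca) + 1L
    for (t in seq_len(Tn - 1L) + 1L)
      s[t] <- findInterval(u[t], cb[s[t - 1L], ]) + 1L
    y <- matrix((runif(Tn * nsp) < model@f[s, , drop = FALSE]) * 1L, Tn, nsp,
                dimnames = list(NULL, model@species@others))
    z <- matrix(NA_integer_, Tn, nsp,
                dimnames = list(NULL, model@species@others))
    al <- y == 1L
    z[al] <- (matrix(runif(Tn * nsp), Tn, nsp)[al] <
              model@g[s, , drop = FALSE][al]) * 1L
    ch <- as.character(seqnames(sl))[i]
    s0 <- start(sl)[i] - 1L
    e0 <- end(sl)[i]
    paths[[i]] <- new("StatePath", chrom = ch, chromStart = s0, chromEnd = e0,
                      states = s, K = K)
    obs[[i]] <- new("ObservationMatrix", chrom = ch, chromStart = s0,
                    chromEnd = e0, y = y, z = z, species = model@species)
  }
  new("SyntheticTruth", model = model, partition = partition, paths = paths,
      obs = obs, seed = as.integer(seed))
}

#' Emit simulated observations as MAF alignment text
#'
#' Draws reference bases uniformly from A/C/G/T; aligned matching species
#' copy the reference base, aligned mismatching species draw uniformly
#' from the other three bases, and unaligned species appear as gaps (or
#' their row is omitted when unaligned throughout a block). Blocks break
#' at runs where no species aligns, and at \code{maxBlock} bases.
#' Ambiguity codes are never emitted, so re-encoding the MAF reproduces
#' the simulated observations exactly:
#' \code{encodeMAF(emitMAF(t), species, partition)} equals \code{t@obs}.
#'
#' @param truth a [SyntheticTruth-class].
#' @param file output MAF path ('.gz' supported).
#' @param seed integer seed for the nucleotide draws.
#' @param maxBlock maximum block length in bases (default 10000).
#' @return The path, invisibly.
#' @export
emitMAF <- function(truth, file, seed = 1L, maxBlock = 10000L) {
  rs <- .seed_guard(seed)
  on.exit(rs())
  bases <- c("A", "C", "G", "T")
  sp <- truth@model@species
  nsp <- length(sp@others)
  chromLen <- truth@partition@chromLengths
  lines <- character(0)
  out <- vector("list", length(truth@obs))
  for (i in seq_along(truth@obs)) {
    o <- truth@obs[[i]]
    Tn <- nrow(o@y)
    ref <- sample(bases, Tn, replace = TRUE)
    chars <- matrix("-", Tn, nsp)
    al <- o@y == 1L
    mt <- al & o@z == 1L
    mm <- al & o@z == 0L
    chars[mt] <- matrix(ref, Tn, nsp)[mt]
    if (any(mm)) {
      ## uniform draw from the three non-reference bases
      refIdx <- match(matrix(ref, Tn, nsp)[mm], bases)
      offs <- sample.int(3L, sum(mm), replace = TRUE)
      chars[mm] <- bases[((refIdx - 1L + offs) %% 4L) + 1L]
    }
    anyAl <- rowSums(al) > 0L
    r <- rle(anyAl)
    ends <- cumsum(r$lengths)
    starts <- c(1L, head(ends, -1L) + 1L)
    blk <- character(0)
    for (j in which(r$values)) {
      for (bs in seq(starts[j], ends[j], by = maxBlock)) {
        be <- min(bs + maxBlock - 1L, ends[j])
        idx <- bs:be
        gStart <- o@chromStart + bs - 1L  # 0-based block start
        bl <- c(sprintf("a score=0.0"),
                sprintf("s %s.%s %s %d + %s %s", sp@reference, o@chrom,
                        format(gStart, scientific = FALSE, trim = TRUE),
                        length(idx),
                        format(chromLen[[o@chrom]], scientific = FALSE,
                               trim = TRUE),
                        paste(ref[idx], collapse = "")))
        for (s in seq_len(nsp)) {
          v <- chars[idx, s]
          nn <- sum(v != "-")
          if (nn == 0L) next  # species unaligned throughout: omit row
          bl <- c(bl, sprintf("s %s.contig 0 %d + %d %s", sp@others[s], nn,
                              nn, paste(v, collapse = "")))
        }
        blk <- c(blk, bl, "")
      }
    }
    out[[i]] <- blk
  }
  con <- if (grepl("\\.gz$", file)) gzfile(file, "wt") else file(file, "wt")
  on.exit(close(con), add = TRUE)
  writeLines(c("##maf version=1 scoring=none", unlist(out)), con)
  invisible(file)
}

#' Deterministic clade-structured preset model
#'
#' A fixed K-state model (K up to 8) over species ordered by divergence
#' from the reference and grouped into three nested clades (close,
#' intermediate, distal — think primates, other mammals, other
#' vertebrates). The state patterns mimic the major kinds of conservation
#' states seen in vertebrate alignments: conserved across all species,
#' conserved within the inner clades only, aligning without matching
#' (high f, low g), essentially unaligned (alignment-artifact-like), and
#' graded intermediates. Transitions are sticky (0.99 self-transition)
#' and the initial distribution is uniform. States are well separated:
#' for K <= 5 every pair of states differs by an emission-vector L1
#' distance of at least 2, making the preset the default truth for
#' parameter-recovery and decoding-accuracy experiments.
#'
#' @param nSpecies number of non-reference species (at least 3).
#' @param K number of states (2 to 8).
#' @return A [ConsModel-class].
#' @examples
#' presetCladeModel(8, 4)
#' @export
presetCladeModel <- function(nSpecies, K) {
  if (K < 2L || K > 8L) stop("the clade preset defines between 2 and 8 states")
  if (nSpecies < 3L) stop("at least 3 species are required (one per clade)")
  nPrim <- ceiling(nSpecies / 3)
  nMam <- ceiling(nSpecies / 3)
  nVert <- nSpecies - nPrim - nMam
  if (nVert < 1L) { nMam <- nMam - 1L; nVert <- 1L }
  clade <- rep(1:3, c(nPrim, nMam, nVert))
  others <- paste0(c("prim", "mam", "vert")[clade],
                   unlist(lapply(c(nPrim, nMam, nVert), seq_len)))
  ## per-state (f, g) by clade: close / intermediate / distal
  fT <- rbind(c(.95, .95, .95),   # 1 conserved across all clades
              c(.95, .95, .10),   # 2 inner-clades conserved
              c(.95, .10, .10),   # 3 close-clade conserved
              c(.90, .90, .90),   # 4 aligns everywhere, rarely matches
              c(.05, .05, .05),   # 5 essentially unaligned (artifact-like)
              c(.90, .90, .10),   # 6 inner clades align, rarely match
              c(.60, .60, .60),   # 7 moderate alignment, high match
              c(.40, .40, .40))   # 8 weak alignment, intermediate match
  gT <- rbind(c(.90, .90, .90),
              c(.90, .85, .50),
              c(.90, .50, .50),
              c(.15, .15, .15),
              c(.50, .50, .50),
              c(.20, .20, .50),
              c(.80, .80, .80),
              c(.55, .55, .55))
  f <- fT[seq_len(K), clade, drop = FALSE]
  g <- gT[seq_len(K), clade, drop = FALSE]
  colnames(f) <- colnames(g) <- others
  b <- matrix(if (K > 1) 0.01 / (K - 1) else 0, K, K)
  diag(b) <- if (K > 1) 0.99 else 1
  ConsModel(SpeciesSet("ref", others), a = rep(1 / K, K), b = b, f = f, g = g)
}

#' Optimal matching of estimated states to true states
#'
#' EM state labels are not identifiable, so recovered parameters are
#' compared to truth after relabeling. Finds the permutation of estimated
#' states minimizing the total L1 distance between the stacked (f, g)
#' emission parameter rows (exhaustive over permutations for K <= 8).
#'
#' @param fitted,truth [ConsModel-class] objects with equal K.
#' @return Integer permutation \code{perm} such that fitted state
#'   \code{perm[k]} corresponds to true state \code{k}.
#' @export
matchStates <- function(fitted, truth) {
  stopifnot(fitted@K == truth@K)
  K <- fitted@K
  if (K > 8L) stop("exhaustive matching supported for K <= 8")
  ef <- cbind(fitted@f, fitted@g)
  et <- cbind(truth@f, truth@g)
  cost <- matrix(0, K, K)  # cost[k, l] = distance of true k to fitted l
  for (k in seq_len(K)) for (l in seq_len(K))
    cost[k, l] <- sum(abs(et[k, ] - ef[l, ]))
  perms <- .permutations(K)
  tot <- vapply(seq_len(nrow(perms)), function(i)
    sum(cost[cbind(seq_len(K), perms[i, ])]), numeric(1))
  unname(perms[which.min(tot), ])
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

#' Relabel a model's states by a permutation
#'
#' @param model a [ConsModel-class].
#' @param perm permutation from [matchStates()]: state k of the result is
#'   state \code{perm[k]} of the input.
#' @return A [ConsModel-class] with reordered states.
#' @export
relabelStates <- function(model, perm) {
  ConsModel(model@species, a = model@a[perm],
            b = model@b[perm, perm, drop = FALSE],
            f = model@f[perm, , drop = FALSE],
            g = model@g[perm, , drop = FALSE])
}
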