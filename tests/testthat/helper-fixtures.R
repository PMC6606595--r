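# Fixtures built in code: small species sets, random valid models and
# observation matrices, and hand-sized segmentations.

library(GenomicRanges)

toySpecies <- function(n = 2) {
  SpeciesSet("ref", paste0("sp", seq_len(n)))
}

# random model with probabilities away from the boundaries
randomValidModel <- function(K, nsp, seed) {
  set.seed(seed)
  sp <- toySpecies(nsp)
  a <- runif(K, 0.1, 1)
  a <- a / sum(a)
  b <- matrix(runif(K * K, 0.1, 1), K, K)
  b <- b / rowSums(b)
  ConsModel(sp, a = a, b = b,
            f = matrix(runif(K * nsp, 0.05, 0.95), K, nsp),
            g = matrix(runif(K * nsp, 0.05, 0.95), K, nsp))
}

randomObs <- function(Tn, nsp, seed, chrom = "chr1", start = 0) {
  set.seed(seed)
  sp <- toySpecies(nsp)
  y <- matrix(rbinom(Tn * nsp, 1, 0.6), Tn, nsp,
              dimnames = list(NULL, sp@others))
  z <- matrix(NA_integer_, Tn, nsp, dimnames = list(NULL, sp@others))
  z[y == 1] <- rbinom(sum(y), 1, 0.5)
  new("ObservationMatrix", chrom = chrom, chromStart = start,
      chromEnd = start + Tn, y = y, z = z, species = sp)
}

# GRanges shorthand
gr <- function(chrom, start, end) GRanges(chrom, IRanges(start, end))
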