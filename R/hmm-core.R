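## Multivariate HMM over per-species align/match observations: emissions,
## scaled forward-backward with missing data, Baum-Welch with per-iteration
## random segment subsampling, likelihood and BIC.

.PROB_FLOOR <- 1e-10
.LOG_FLOOR <- 1e-300  # avoids 0 * -Inf = NaN inside BLAS products

#' Emission probability of one position's observation vector
#'
#' The probability, under state \code{k}, of the observation vector of one
#' position: the product over species of the per-species observation
#' probability. Two equivalent forms are available: the two-Bernoulli form
#' f^y * (g^z (1-g)^(1-z))^y * (1-f)^(1-y), where a missing z (unaligned
#' species) contributes no match factor, and the three-way multinomial form
#' using p1 = f*g, p2 = f*(1-g), p3 = 1-f.
#'
#' @param model a [ConsModel-class].
#' @param k state index.
#' @param y binary align vector (length N-1).
#' @param z match vector in \{0,1,NA\}; must be NA exactly where y is 0.
#' @param form \code{"bernoulli"} (default) or \code{"multinomial"}.
#' @return The emission probability.
#' @examples
#' sp <- SpeciesSet("hg", "sp1")
#' m <- ConsModel(sp, a = 1, b = matrix(1, 1, 1),
#'                f = matrix(.8, 1, 1), g = matrix(.75, 1, 1))
#' emissionProb(m, 1, y = 1, z = 1)   # f*g   = 0.6
#' emissionProb(m, 1, y = 1, z = 0)   # f*(1-g) = 0.2
#' emissionProb(m, 1, y = 0, z = NA)  # 1-f   = 0.2
#' @export
emissionProb <- function(model, k, y, z,
                         form = c("bernoulli", "multinomial")) {
  form <- match.arg(form)
  stopifnot(is(model, "ConsModel"), k >= 1, k <= model@K)
  if (!identical(is.na(z), y == 0))
    stop("inconsistent observation: z must be missing exactly where y = 0")
  f <- model@f[k, ]
  g <- model@g[k, ]
  if (form == "bernoulli") {
    match_factor <- ifelse(is.na(z), 1, g^ifelse(is.na(z), 0, z) *
                                        (1 - g)^ifelse(is.na(z), 0, 1 - z))
    prod(f^y * match_factor^y * (1 - f)^(1 - y))
  } else {
    m <- ifelse(y == 0, 3L, ifelse(z == 1, 1L, 2L))
    p <- cbind(f * g, f * (1 - g), 1 - f)
    prod(p[cbind(seq_along(m), m)])
  }
}

## T x K matrix of log emission probabilities for a whole slice, computed as
## three indicator-matrix products (BLAS) against the per-state log
## parameters. Missing z contributes no factor by construction.
.log_emission_matrix <- function(model, obs) {
  A <- (obs@y == 1L & !is.na(obs@z) & obs@z == 1L) * 1  # align + match
  B <- (obs@y == 1L & !is.na(obs@z) & obs@z == 0L) * 1  # align + mismatch
  C <- (obs@y == 0L) * 1                                # unaligned
  L1 <- log(pmax(model@f * model@g, .LOG_FLOOR))
  L2 <- log(pmax(model@f * (1 - model@g), .LOG_FLOOR))
  L3 <- log(pmax(1 - model@f, .LOG_FLOOR))
  A %*% t(L1) + B %*% t(L2) + C %*% t(L3)
}

#' Forward-backward inference for one slice
#'
#' Exact marginal posterior state probabilities and the log-likelihood of a
#' slice, treating the slice as an independent sequence whose first base
#' receives the initial distribution. The recursion uses per-position
#' scaling in linear space, with log emissions shifted by their row maximum
#' before exponentiation, and is stable for hundreds of species and
#' megabase slices.
#'
#' @param model a [ConsModel-class].
#' @param obs an [ObservationMatrix-class] with the same species set.
#' @return A [PosteriorMatrix-class].
#' @export
forwardBackward <- function(model, obs) {
  stopifnot(is(model, "ConsModel"), is(obs, "ObservationMatrix"))
  if (!identical(model@species@others, obs@species@others))
    stop("model and observation species sets differ")
  logE <- .log_emission_matrix(model, obs)
  r <- fb_core(logE, model@a, model@b)
  new("PosteriorMatrix", chrom = obs@chrom, chromStart = obs@chromStart,
      chromEnd = obs@chromEnd, values = r$gamma, loglik = r$loglik,
      loglikBackward = r$loglikBackward)
}

#' Total log-likelihood of a collection of slices
#'
#' Sum of per-slice log-likelihoods; each slice is modelled as an
#' independent sequence. An empty collection has log-likelihood 0.
#'
#' @param model a [ConsModel-class].
#' @param obsList list of [ObservationMatrix-class].
#' @return Numeric scalar.
#' @export
logLikelihood <- function(model, obsList) {
  if (is(obsList, "ObservationMatrix")) obsList <- list(obsList)
  if (!length(obsList)) return(0)
  sum(vapply(obsList, function(o) forwardBackward(model, o)@loglik,
             numeric(1)))
}

#' Bayesian Information Criterion of a fitted model
#'
#' BIC = -2 loglik + P log(T), with free-parameter count
#' P = (K-1) + K(K-1) + 2K(N-1) (initial distribution, transition rows,
#' and the per-state per-species align and match probabilities) and T the
#' total number of scored positions.
#'
#' @inheritParams logLikelihood
#' @return Numeric scalar (lower is better).
#' @export
bic <- function(model, obsList) {
  if (is(obsList, "ObservationMatrix")) obsList <- list(obsList)
  K <- model@K
  nsp <- length(model@species@others)
  P <- (K - 1) + K * (K - 1) + 2 * K * nsp
  Ttot <- sum(vapply(obsList, function(o) nrow(o@y), numeric(1)))
  -2 * logLikelihood(model, obsList) + P * log(Ttot)
}

#' Seeded random model initialization
#'
#' Symmetry-breaking starting point for [baumWelch()]: f and g drawn from
#' Uniform(0.2, 0.8), uniform initial distribution, transitions 0.9 on the
#' diagonal with the remaining mass spread uniformly off-diagonal.
#'
#' @param K number of states.
#' @param species a [SpeciesSet-class].
#' @param seed integer RNG seed.
#' @return A [ConsModel-class].
#' @export
randomModel <- function(K, species, seed = 1L) {
  nsp <- length(species@others)
  rs <- .seed_guard(seed)
  on.exit(rs())
  f <- matrix(runif(K * nsp, 0.2, 0.8), K, nsp)
  g <- matrix(runif(K * nsp, 0.2, 0.8), K, nsp)
  b <- matrix(if (K > 1) 0.1 / (K - 1) else 0, K, K)
  diag(b) <- if (K > 1) 0.9 else 1
  ConsModel(species, a = rep(1 / K, K), b = b, f = f, g = g)
}

## set.seed scoped to the calling computation; restores the caller's RNG
.seed_guard <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}

.clamp <- function(x, lo = .PROB_FLOOR, hi = 1 - .PROB_FLOOR) {
  pmin(pmax(x, lo), hi)
}

#' Baum-Welch training with random segment subsampling
#'
#' Runs exactly \code{nIterations} EM iterations. Each iteration samples
#' \code{min(segmentsPerIteration, number of slices)} slices uniformly
#' without replacement with the seeded RNG, accumulates expected counts over
#' the sampled slices only, and re-estimates all parameters. There is no
#' likelihood-based stopping rule: with subsampling the likelihood is
#' expected to move both up and down between iterations. With
#' \code{segmentsPerIteration >= length(obsList)} every iteration uses the
#' full data and the log-likelihood trajectory is non-decreasing (standard
#' EM guarantee). The conditional match probability g is re-estimated only
#' from (expected) aligned positions; unaligned positions contribute no
#' match information. Parameters are floored to [1e-10, 1-1e-10] after each
#' M-step (then renormalized), preventing absorbing zeros under
#' subsampling. Identical seed and inputs give bitwise-identical parameter
#' trajectories.
#'
#' @param init starting [ConsModel-class] (e.g. from [randomModel()]).
#' @param obsList list of [ObservationMatrix-class] slices.
#' @param nIterations number of EM iterations (default 200).
#' @param segmentsPerIteration slices sampled per iteration (default 150).
#' @param seed integer RNG seed for the subsampling.
#' @return The fitted [ConsModel-class]; \code{@fitInfo$loglik} holds the
#'   per-iteration total log-likelihood of the slices used in that
#'   iteration (computed with the pre-update parameters).
#' @export
baumWelch <- function(init, obsList, nIterations = 200L,
                      segmentsPerIteration = 150L, seed = 1L) {
  stopifnot(is(init, "ConsModel"))
  if (is(obsList, "ObservationMatrix")) obsList <- list(obsList)
  if (nIterations < 1L) stop("nIterations must be at least 1")
  if (!length(obsList)) stop("at least one slice is required")
  n <- length(obsList)
  nSamp <- min(segmentsPerIteration, n)
  K <- init@K
  nsp <- length(init@species@others)
  ## per-slice sufficient statistics of the observations, computed once
  stat <- lapply(obsList, function(o) {
    A <- (o@y == 1L & !is.na(o@z) & o@z == 1L) * 1
    B <- (o@y == 1L & !is.na(o@z) & o@z == 0L) * 1
    list(A = A, B = B, C = (o@y == 0L) * 1)
  })
  rs <- .seed_guard(seed)
  on.exit(rs())
  model <- init
  llTrace <- numeric(nIterations)
  for (it in seq_len(nIterations)) {
    idx <- if (nSamp >= n) seq_len(n) else sort(sample.int(n, nSamp))
    L1 <- log(pmax(model@f * model@g, .LOG_FLOOR))
    L2 <- log(pmax(model@f * (1 - model@g), .LOG_FLOOR))
    L3 <- log(pmax(1 - model@f, .LOG_FLOOR))
    aNum <- numeric(K)
    bNum <- matrix(0, K, K)
    gammaSum <- numeric(K)
    fNum <- matrix(0, K, nsp)   # E[#aligned | state]
    gNum <- matrix(0, K, nsp)   # E[#aligned & matched | state]
    ll <- 0
    for (s in idx) {
      st <- stat[[s]]
      logE <- st$A %*% t(L1) + st$B %*% t(L2) + st$C %*% t(L3)
      r <- fb_core(logE, model@a, model@b)
      gam <- r$gamma
      ll <- ll + r$loglik
      aNum <- aNum + gam[1L, ]
      bNum <- bNum + r$xiSum
      gammaSum <- gammaSum + colSums(gam)
      tg <- t(gam)
      fNum <- fNum + tg %*% (st$A + st$B)
      gNum <- gNum + tg %*% st$A
    }
    llTrace[it] <- ll
    a <- .clamp(aNum / sum(aNum))
    a <- a / sum(a)
    b <- if (K > 1) .clamp(bNum / rowSums(bNum)) else matrix(1, 1, 1)
    b <- b / rowSums(b)
    f <- .clamp(fNum / gammaSum)
    g <- .clamp(gNum / pmax(fNum, .LOG_FLOOR))
    model <- ConsModel(init@species, a = a, b = b, f = f, g = g)
  }
  model@fitInfo <- list(loglik = llTrace, nIterations = nIterations,
                        segmentsPerIteration = segmentsPerIteration,
                        seed = as.integer(seed))
  model
}

#' Fit a conservation-state model with short-run restarts
#'
#' The recommended training entry point. EM on sticky-transition HMMs has
#' strong local optima, so a single random start is unreliable:
#' \code{fitModel} runs \code{nRestarts} short EM bursts of
#' \code{burnIterations} each from distinct seeded random initializations
#' (seeds derived deterministically from \code{seed}), keeps the
#' initialization with the highest burn-in log-likelihood, and continues it
#' for the remaining \code{nIterations - burnIterations} iterations. The
#' whole procedure is reproducible given \code{seed}.
#'
#' @param obsList list of [ObservationMatrix-class] slices.
#' @param K number of states.
#' @inheritParams baumWelch
#' @param nRestarts number of random initializations tried (default 8).
#' @param burnIterations EM iterations per burn-in run (default 20).
#' @return The fitted [ConsModel-class]; \code{@fitInfo} carries the
#'   concatenated log-likelihood trajectory of the winning run and the
#'   burn-in final log-likelihoods of all restarts.
#' @export
fitModel <- function(obsList, K, nIterations = 200L,
                     segmentsPerIteration = 150L, seed = 1L,
                     nRestarts = 8L, burnIterations = 20L) {
  if (is(obsList, "ObservationMatrix")) obsList <- list(obsList)
  species <- obsList[[1L]]@species
  burnIterations <- min(burnIterations, nIterations)
  restartSeeds <- as.integer(seed) + 7919L * seq_len(nRestarts)
  burns <- lapply(restartSeeds, function(s)
    baumWelch(randomModel(K, species, seed = s), obsList,
              nIterations = burnIterations,
              segmentsPerIteration = segmentsPerIteration, seed = s))
  burnLL <- vapply(burns, function(m) tail(m@fitInfo$loglik, 1L), numeric(1))
  best <- burns[[which.max(burnLL)]]
  remaining <- nIterations - burnIterations
  fit <- if (remaining > 0)
    baumWelch(best, obsList, nIterations = remaining,
              segmentsPerIteration = segmentsPerIteration, seed = seed)
  else best
  fit@fitInfo <- list(
    loglik = c(best@fitInfo$loglik,
               if (remaining > 0) fit@fitInfo$loglik else numeric(0)),
    nIterations = nIterations,
    segmentsPerIteration = segmentsPerIteration,
    seed = as.integer(seed), burnLoglik = burnLL,
    chosenRestart = which.max(burnLL))
  fit
}

#' Write / read a model file
#'
#' Tab-separated sections for K, the reference and species order, the
#' initial distribution, the transition matrix, and the per-state
#' per-species align (f) and conditional match (g) probabilities. Values
#' are printed with \code{\%.17g}, so the round trip is exact.
#'
#' @param model a [ConsModel-class].
#' @param file path ('.gz' supported).
#' @return \code{writeModel}: the path, invisibly; \code{readModel}: a
#'   [ConsModel-class].
#' @export
writeModel <- function(model, file) {
  stopifnot(is(model, "ConsModel"))
  nsp <- length(model@species@others)
  fmt <- function(x) sprintf("%.17g", x)
  out <- c(
    paste0("K\t", model@K),
    paste0("reference\t", model@species@reference),
    paste0("species\t", paste(model@species@others, collapse = ",")),
    paste("a", seq_len(model@K), fmt(model@a), sep = "\t"),
    paste("b", rep(seq_len(model@K), model@K),
          rep(seq_len(model@K), each = model@K),
          fmt(as.vector(model@b)), sep = "\t"),
    paste("f", rep(seq_len(model@K), nsp),
          rep(model@species@others, each = model@K),
          fmt(as.vector(model@f)), sep = "\t"),
    paste("g", rep(seq_len(model@K), nsp),
          rep(model@species@others, each = model@K),
          fmt(as.vector(model@g)), sep = "\t"))
  con <- if (grepl("\\.gz$", file)) gzfile(file, "wt") else file(file, "wt")
  on.exit(close(con))
  writeLines(out, con)
  invisible(file)
}

#' @rdname writeModel
#' @export
readModel <- function(file) {
  con <- .open_text(file)
  on.exit(close(con))
  lines <- readLines(con)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  tag <- vapply(fields, `[[`, character(1), 1L)
  getv <- function(t) fields[tag == t]
  K <- as.integer(getv("K")[[1L]][2L])
  reference <- getv("reference")[[1L]][2L]
  others <- strsplit(getv("species")[[1L]][2L], ",", fixed = TRUE)[[1L]]
  sp <- SpeciesSet(reference, others)
  nsp <- length(others)
  a <- numeric(K)
  for (r in getv("a")) a[as.integer(r[2L])] <- as.numeric(r[3L])
  b <- matrix(0, K, K)
  for (r in getv("b")) b[as.integer(r[2L]), as.integer(r[3L])] <- as.numeric(r[4L])
  f <- matrix(0, K, nsp, dimnames = list(NULL, others))
  g <- matrix(0, K, nsp, dimnames = list(NULL, others))
  for (r in getv("f")) f[as.integer(r[2L]), r[3L]] <- as.numeric(r[4L])
  for (r in getv("g")) g[as.integer(r[2L]), r[3L]] <- as.numeric(r[4L])
  ConsModel(sp, a = a, b = b, f = f, g = g)
}
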