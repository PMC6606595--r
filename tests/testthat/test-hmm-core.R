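# Emission parameterization, forward-backward against brute-force path
# enumeration, Baum-Welch behavior, BIC, and model file round trips.

test_that("emission probabilities follow the two-Bernoulli definition", {
  sp <- toySpecies(1)
  m <- ConsModel(sp, a = 1, b = matrix(1, 1, 1),
                 f = matrix(0.8, 1, 1), g = matrix(0.75, 1, 1))
  expect_equal(emissionProb(m, 1, 1, 1), 0.6)    # f*g
  expect_equal(emissionProb(m, 1, 1, 0), 0.2)    # f*(1-g)
  expect_equal(emissionProb(m, 1, 0, NA), 0.2)   # 1-f
  # degenerate: deterministic emissions
  m1 <- ConsModel(toySpecies(3), a = 1, b = matrix(1, 1, 1),
                  f = matrix(1, 1, 3), g = matrix(1, 1, 3))
  expect_equal(emissionProb(m1, 1, c(1, 1, 1), c(1, 1, 1)), 1)
  # product over species
  m2 <- ConsModel(toySpecies(2), a = 1, b = matrix(1, 1, 1),
                  f = matrix(0.5, 1, 2), g = matrix(0.5, 1, 2))
  expect_equal(emissionProb(m2, 1, c(1, 0), c(1, NA)), 0.25 * 0.5)
  expect_error(emissionProb(m2, 1, c(1, 0), c(1, 0)), "inconsistent")
})

test_that("two-Bernoulli and multinomial emission forms agree to 1e-12", {
  set.seed(7)
  m <- randomValidModel(3, 5, seed = 7)
  p <- emissionMultinomial(m)
  # the three outcome probabilities sum to 1 exactly for every (k, j)
  expect_true(all(p[, , 1] + p[, , 2] + p[, , 3] == 1))
  for (i in seq_len(200)) {
    y <- rbinom(5, 1, 0.5)
    z <- ifelse(y == 1, rbinom(5, 1, 0.5), NA)
    k <- sample(3, 1)
    expect_equal(emissionProb(m, k, y, z, form = "bernoulli"),
                 emissionProb(m, k, y, z, form = "multinomial"),
                 tolerance = 1e-12)
  }
})

test_that("forward-backward matches brute-force path enumeration", {
  for (seed in 1:6) {
    K <- sample(2:3, 1)
    m <- randomValidModel(K, nsp = sample(2:4, 1), seed = seed)
    obs <- randomObs(sample(5:8, 1), ncol(m@f), seed = seed + 100)
    bf <- bruteForceHMM(m, obs)
    fb <- forwardBackward(m, obs)
    expect_equal(fb@loglik, bf$loglik, tolerance = 1e-9)
    expect_equal(unname(fb@values), bf$gamma, tolerance = 1e-9)
    # forward and backward logliks agree
    expect_equal(fb@loglik, fb@loglikBackward, tolerance = 1e-6)
    expect_equal(rowSums(fb@values), rep(1, nrow(obs@y)), tolerance = 1e-9)
  }
})

test_that("single state and symmetric models give trivial posteriors", {
  m1 <- randomValidModel(1, 2, seed = 3)
  obs <- randomObs(50, 2, seed = 4)
  fb <- forwardBackward(m1, obs)
  expect_true(all(fb@values == 1))
  ll <- sum(vapply(seq_len(50), function(t)
    log(emissionProb(m1, 1, obs@y[t, ], obs@z[t, ])), numeric(1)))
  expect_equal(fb@loglik, ll, tolerance = 1e-9)
  # identical emissions across states: posterior 1/K everywhere
  sp <- toySpecies(2)
  m2 <- ConsModel(sp, a = c(.5, .5), b = matrix(.5, 2, 2),
                  f = matrix(.6, 2, 2), g = matrix(.4, 2, 2))
  fb2 <- forwardBackward(m2, obs)
  expect_equal(unname(fb2@values), matrix(0.5, 50, 2), tolerance = 1e-12)
})

test_that("forward-backward is numerically stable with many species", {
  # 99 species, extreme parameters: posteriors must not underflow to NaN
  nsp <- 99
  sp <- toySpecies(nsp)
  set.seed(9)
  m <- ConsModel(sp, a = c(.5, .5),
                 b = matrix(c(.999, .001, .001, .999), 2, 2, byrow = TRUE),
                 f = matrix(c(rep(1 - 1e-10, nsp), rep(1e-10, nsp)),
                            2, nsp, byrow = TRUE),
                 g = matrix(0.5, 2, nsp))
  obs <- randomObs(2000, nsp, seed = 10)
  fb <- forwardBackward(m, obs)
  expect_false(anyNA(fb@values))
  expect_true(is.finite(fb@loglik))
})

test_that("K=1 EM recovers empirical align/match frequencies", {
  sp <- toySpecies(2)
  m0 <- ConsModel(sp, a = 1, b = matrix(1, 1, 1),
                  f = matrix(.5, 1, 2), g = matrix(.5, 1, 2))
  obs <- randomObs(4000, 2, seed = 5)
  fit <- baumWelch(m0, list(obs), nIterations = 2,
                   segmentsPerIteration = 1, seed = 1)
  expect_equal(as.vector(fit@f), unname(colMeans(obs@y)), tolerance = 1e-8)
  empG <- vapply(1:2, function(j)
    mean(obs@z[obs@y[, j] == 1, j]), numeric(1))
  expect_equal(as.vector(fit@g), empG, tolerance = 1e-8)
})

test_that("full-data Baum-Welch log-likelihood is non-decreasing", {
  model <- presetCladeModel(4, 3)
  part <- GenomePartition(c(chr1 = 6000), sliceLength = 2000)
  truth <- simulateAlignment(model, part, seed = 13)
  fit <- baumWelch(randomModel(3, model@species, seed = 2), truth@obs,
                   nIterations = 40, segmentsPerIteration = 3, seed = 1)
  expect_true(all(diff(fit@fitInfo$loglik) >= -1e-8))
})

test_that("subsampled training is bitwise reproducible given the seed", {
  model <- presetCladeModel(4, 2)
  part <- GenomePartition(c(chr1 = 5000), sliceLength = 500)
  truth <- simulateAlignment(model, part, seed = 17)
  init <- randomModel(2, model@species, seed = 3)
  f1 <- baumWelch(init, truth@obs, nIterations = 15,
                  segmentsPerIteration = 2, seed = 99)
  f2 <- baumWelch(init, truth@obs, nIterations = 15,
                  segmentsPerIteration = 2, seed = 99)
  expect_identical(f1@f, f2@f)
  expect_identical(f1@g, f2@g)
  expect_identical(f1@b, f2@b)
  expect_identical(f1@fitInfo$loglik, f2@fitInfo$loglik)
  # a different seed samples different segments
  f3 <- baumWelch(init, truth@obs, nIterations = 15,
                  segmentsPerIteration = 2, seed = 100)
  expect_false(identical(f1@f, f3@f))
  expect_error(baumWelch(init, truth@obs, nIterations = 0), "at least 1")
})

test_that("BIC counts free parameters and penalizes by scored positions", {
  m <- randomValidModel(1, 1, seed = 19)
  obs <- randomObs(10, 1, seed = 20)
  # K=1, one species: P = 2
  expect_equal(bic(m, obs), -2 * logLikelihood(m, obs) + 2 * log(10))
  m2 <- randomValidModel(2, 3, seed = 21)
  obs2 <- randomObs(8, 3, seed = 22)
  P <- (2 - 1) + 2 * (2 - 1) + 2 * 2 * 3
  expect_equal(bic(m2, obs2),
               -2 * bruteForceHMM(m2, obs2)$loglik + P * log(8),
               tolerance = 1e-9)
  expect_equal(logLikelihood(m, list()), 0)
})

test_that("a refined larger model never has lower log-likelihood", {
  # duplicate a fitted K-state model into K+1 states with a tiny
  # perturbation: the refinement starts at (essentially) the same
  # likelihood, and EM from it can only go up
  model <- presetCladeModel(4, 2)
  part <- GenomePartition(c(chr1 = 4000), sliceLength = 4000)
  truth <- simulateAlignment(model, part, seed = 23)
  fitK <- baumWelch(randomModel(2, model@species, seed = 1), truth@obs,
                    nIterations = 30, segmentsPerIteration = 1, seed = 1)
  llK <- logLikelihood(fitK, truth@obs)
  K1 <- 3
  a <- c(fitK@a, 1e-8)
  a <- a / sum(a)
  b <- rbind(cbind(fitK@b * (1 - 1e-8), 1e-8), c(fitK@b[1, ] * (1 - 1e-8), 1e-8))
  b <- b / rowSums(b)
  refined <- ConsModel(model@species, a = a, b = b,
                       f = rbind(fitK@f, fitK@f[1, ]),
                       g = rbind(fitK@g, fitK@g[1, ]))
  fitK1 <- baumWelch(refined, truth@obs, nIterations = 10,
                     segmentsPerIteration = 1, seed = 1)
  expect_gte(logLikelihood(fitK1, truth@obs), llK - 1e-6)
})

test_that("model files round-trip exactly", {
  m <- randomValidModel(3, 4, seed = 29)
  f <- tempfile(fileext = ".tsv")
  writeModel(m, f)
  back <- readModel(f)
  expect_identical(back@a, m@a)
  expect_identical(unname(back@b), unname(m@b))
  expect_identical(unname(back@f), unname(m@f))
  expect_identical(unname(back@g), unname(m@g))
  expect_identical(back@species@others, m@species@others)
})

test_that("fitModel restarts are reproducible and pick the best burn-in", {
  model <- presetCladeModel(4, 2)
  part <- GenomePartition(c(chr1 = 4000), sliceLength = 1000)
  truth <- simulateAlignment(model, part, seed = 31)
  f1 <- fitModel(truth@obs, K = 2, nIterations = 25,
                 segmentsPerIteration = 4, seed = 5, nRestarts = 3,
                 burnIterations = 10)
  f2 <- fitModel(truth@obs, K = 2, nIterations = 25,
                 segmentsPerIteration = 4, seed = 5, nRestarts = 3,
                 burnIterations = 10)
  expect_identical(f1@f, f2@f)
  expect_length(f1@fitInfo$burnLoglik, 3L)
  expect_length(f1@fitInfo$loglik, 25L)
})
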