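test_that("single-step operations respect their contracts", {
  hyp <- modelHyperparameters()
  # Dirichlet(1,1,1,1): uniform simplex draws
  set.seed(2)
  hypFlat <- modelHyperparameters(alpha1 = 1, alpha2 = 1, alpha3 = 1,
                                  alpha4 = 1,
                                  link = linkFunction("constant",
                                                      targetMean = 1e-8))
  draws <- t(replicate(4000, gibbsStepTheta(c(0, 0, 0, 0), 0.5, hypFlat)))
  expect_equal(colMeans(draws), rep(0.25, 4), tolerance = 0.02)
  # huge counts: concentration at the normalized counts
  big <- gibbsStepTheta(c(4e6, 3e6, 2e6, 1e6), 0.5, hyp)
  expect_equal(big, c(0.4, 0.3, 0.2, 0.1), tolerance = 5e-3)
  # moment oracle
  sh <- conditionalThetaParams(c(40, 30, 20, 110), 0.5, hyp)
  dr <- t(replicate(20000, gibbsStepTheta(c(40, 30, 20, 110), 0.5, hyp)))
  a0 <- sum(sh)
  expect_equal(colMeans(dr), sh / a0, tolerance = 0.01)
  expect_equal(apply(dr, 2, var), sh * (a0 - sh) / (a0^2 * (a0 + 1)),
               tolerance = 0.1)

  # Metropolis: out-of-bounds proposals always rejected
  set.seed(5)
  res <- replicate(200, {
    r <- metropolisStepPi(0.01, jumpSd = 5, theta = c(0.3, 0.2, 0.2, 0.3),
                          Sall = 100, hyp)
    c(r$pi, r$accepted)
  })
  rejectedOut <- res[1, res[2, ] == 0]
  expect_true(all(rejectedOut == 0.01))
})

test_that("chains are deterministic given the seed", {
  sim <- simulatePairDataset(N = 4, seed = 30)
  st <- chainSettings(1000L, 200L, seed = 99L)
  p1 <- runPairChain(sim$Z, sim$S, settings = st)
  p2 <- runPairChain(sim$Z, sim$S, settings = st)
  expect_identical(thetaSamples(p1), thetaSamples(p2))
  expect_identical(piSamples(p1), piSamples(p2))
  expect_identical(acceptanceRate(p1), acceptanceRate(p2))
})

test_that("with a constant link the chain recovers the conjugate posterior", {
  hypC <- modelHyperparameters(link = linkFunction("constant"))
  set.seed(8)
  Z <- t(rmultinom(3, 100, c(0.3, 0.2, 0.2, 0.3)))
  S <- c(120, 90, 90)                       # sum 300, N = 3, M = 1000
  pp <- runPairChain(Z, S, hypC, chainSettings(20000L, 2000L, seed = 17L))

  piMean <- mean(piSamples(pp))
  expect_equal(301 / 3002, 0.10027, tolerance = 1e-4)
  expect_lt(abs(piMean - 301 / 3002), 3 * mcse(piSamples(pp)))

  dpar <- colSums(Z) + c(10 + 5, 10, 10, 10)
  thMean <- colMeans(thetaSamples(pp))
  for (i in 1:4)
    expect_lt(abs(thMean[i] - dpar[i] / sum(dpar)),
              3 * mcse(thetaSamples(pp)[, i]))
  # second moment too
  a0 <- sum(dpar)
  expect_equal(var(thetaSamples(pp)[, 1]),
               dpar[1] * (a0 - dpar[1]) / (a0^2 * (a0 + 1)),
               tolerance = 0.15)
})

test_that("adaptation lands the acceptance rate near its target", {
  rates <- vapply(1:8, function(i) {
    sim <- simulatePairDataset(N = c(15L, 30L, 100L)[1 + i %% 3], seed = 100 + i)
    acceptanceRate(runPairChain(sim$Z, sim$S,
                                settings = chainSettings(2000L, 500L,
                                                         seed = 200 + i)))
  }, numeric(1))
  expect_true(all(rates >= 0.15 & rates <= 0.40))
})

test_that("structural counts pull the posterior of theta1 upward", {
  set.seed(21)
  Z <- t(rmultinom(10, 100, c(0.25, 0.25, 0.25, 0.25)))
  means <- vapply(c(50, 2000, 6000, 9500), function(Ssum) {
    S <- rep(Ssum / 10, 10)
    pp <- runPairChain(Z, S, settings = chainSettings(4000L, 1000L, seed = 3L))
    mean(thetaSamples(pp)[, 1])
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("fitAllPairs is order-invariant and handles missing structural data", {
  hyp <- modelHyperparameters()
  st <- chainSettings(500L, 100L, seed = 42L)
  sims <- lapply(1:3, function(i) simulatePairDataset(N = 3, seed = 300 + i))
  Zl <- lapply(sims, `[[`, "Z")
  Sl <- lapply(sims, `[[`, "S")
  pairs <- cbind(c("A", "A", "B"), c("B", "C", "C"))
  f1 <- fitAllPairs(Zl, Sl, pairs, hyp, st)
  f2 <- fitAllPairs(Zl[c(2, 1, 3)], Sl[c(2, 1, 3)], pairs[c(2, 1, 3), ],
                    hyp, st)
  # pair 2 fitted first or second gives different per-pair seeds by index,
  # so compare pair 3 which keeps its index
  expect_identical(thetaSamples(f1[[3]]), thetaSamples(f2[[3]]))
  expect_identical(names(f1), c("A--B", "A--C", "B--C"))

  expect_error(fitAllPairs(Zl, list(Sl[[1]], NULL, Sl[[3]]), pairs, hyp, st),
               "missing structural")
  expect_message(
    f3 <- fitAllPairs(Zl, list(Sl[[1]], NULL, Sl[[3]]), pairs, hyp, st,
                      missingStructural = "flat-prior"),
    "flat-prior")
  # fallback pair: pi sampled from its flat prior, centered near 0.5
  expect_equal(mean(piSamples(f3[[2]])), 0.5, tolerance = 0.15)
})

test_that("simulation-based calibration ranks are uniform", {
  r <- sbcRanks(nReplicates = 200L, seed = 5L)
  bins <- 10L
  for (col in c("rankPi", "rankTheta1")) {
    b <- floor(r[[col]] / ((r$nKept[1] + 1) / bins))
    b[b >= bins] <- bins - 1L
    p <- chisq.test(tabulate(b + 1L, bins))$p.value
    expect_gt(p, 0.01)
  }
})
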