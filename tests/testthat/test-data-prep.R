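test_that("dominant profile matches an eigendecomposition oracle", {
  set.seed(42)
  x <- matrix(rnorm(50), 10, 5)
  u <- extractDominantProfile(x)
  # oracle: leading eigenvector of the 10x10 cross-product matrix
  ev <- eigen(x %*% t(x), symmetric = TRUE)$vectors[, 1]
  if (sum(ev * (rowMeans(x) - mean(rowMeans(x)))) < 0) ev <- -ev
  expect_equal(u, ev, tolerance = 1e-10)
  expect_equal(sum(u^2), 1, tolerance = 1e-12)

  # one voxel: the column itself, unit norm, positively aligned
  v <- rnorm(8) + 3
  u1 <- extractDominantProfile(matrix(v, ncol = 1))
  expect_equal(u1, v / sqrt(sum(v^2)), tolerance = 1e-12)

  # two identical columns: still the column direction
  u2 <- extractDominantProfile(cbind(v, v))
  expect_equal(abs(cor(u2, v)), 1, tolerance = 1e-12)
  expect_gt(cor(u2, v), 0)

  # explicit reference overrides the voxel mean for the sign rule
  u3 <- extractDominantProfile(matrix(v, ncol = 1), referenceMean = -v)
  expect_equal(u3, -v / sqrt(sum(v^2)), tolerance = 1e-12)

  expect_error(extractDominantProfile(matrix(0, 5, 3)), "degenerate")
})

test_that("dichotomization thresholds at c standard deviations above the mean", {
  b <- dichotomize(c(2, 0, 2, 0), c = 0.01)
  expect_identical(as.integer(b), c(1L, 0L, 1L, 0L))
  expect_equal(attr(b, "mean"), 1)
  expect_equal(attr(b, "sd"), sd(c(2, 0, 2, 0)))  # sample formula

  expect_warning(bc <- dichotomize(rep(3, 10)), "degenerate")
  expect_identical(as.integer(bc), integer(10))
  expect_true(attr(bc, "degenerate"))

  set.seed(7)
  v <- rnorm(200)
  b0 <- dichotomize(v, c = 0)
  expect_identical(as.integer(b0), as.integer(v - mean(v) > 0))  # count oracle
})

test_that("joint activation counts cross-tabulate the indicator pair", {
  expect_identical(jointActivationCounts(c(1, 1, 0, 0, 1), c(1, 0, 1, 0, 1)),
                   c(2L, 1L, 1L, 1L))
  a <- c(1L, 0L, 1L, 1L, 0L)
  expect_identical(jointActivationCounts(a, a), c(3L, 0L, 0L, 2L))
  expect_error(jointActivationCounts(c(1, 0), c(1, 0, 1)), "length")

  set.seed(1)
  for (r in 1:5) {
    x <- rbinom(50, 1, 0.4); y <- rbinom(50, 1, 0.6)
    z <- c(0L, 0L, 0L, 0L)                     # brute-force loop oracle
    for (t in 1:50) {
      cell <- if (x[t] && y[t]) 1 else if (x[t]) 2 else if (y[t]) 3 else 4
      z[cell] <- z[cell] + 1L
    }
    expect_identical(jointActivationCounts(x, y), z)
    # swapping the regions swaps Z2 and Z3
    expect_identical(jointActivationCounts(y, x), z[c(1, 3, 2, 4)])
  }
})

test_that("count rescaling uses largest-remainder allocation summing to T", {
  expect_identical(rescaleJointCounts(c(100, 100, 100, 183), T = 100L),
                   c(21L, 21L, 20L, 38L))
  expect_identical(rescaleJointCounts(c(3, 5, 7, 10), T = 25L), c(3L, 5L, 7L, 10L))
  expect_identical(rescaleJointCounts(c(483, 0, 0, 0), T = 100L),
                   c(100L, 0L, 0L, 0L))
  expect_error(rescaleJointCounts(c(0, 0, 0, 0), T = 100L), "Tstar")

  set.seed(3)
  for (r in 1:200) {
    raw <- rmultinom(1, sample(50:600, 1), runif(4))[, 1]
    out <- rescaleJointCounts(raw, T = 100L)
    expect_identical(sum(out), 100L)
    expect_true(all(out >= 0L))
    # allocation never deviates from the exact share by 1 or more
    expect_true(all(abs(out - raw * 100 / sum(raw)) < 1))
  }
})

test_that("structural aggregation: quantile, symmetrization, scan averaging", {
  expect_equal(aggregateDirectionalCounts(c(0, 0, 100, 200, 1000), q = 0.9), 680)
  expect_equal(aggregateDirectionalCounts(rep(7, 5)), 7)
  expect_equal(aggregateDirectionalCounts(c(3, 9, 1), q = 1), 9)
  expect_error(aggregateDirectionalCounts(numeric(0)), "non-empty")

  expect_equal(symmetrizePairCounts(680, 500), 680)
  expect_equal(symmetrizePairCounts(0, 7), 7)
  expect_equal(symmetrizePairCounts(4, 4), 4)
  expect_identical(symmetrizePairCounts(123, 45), symmetrizePairCounts(45, 123))
  expect_error(symmetrizePairCounts(-1, 3), "non-negative")

  cs <- combineScansAndRescale(c(680, 700), Mstar = 5000, M = 1000L)
  expect_equal(cs$Sstar, 690)
  expect_identical(cs$S, 138L)
  expect_identical(combineScansAndRescale(412.4, Mstar = 1000, M = 1000L)$S, 412L)
  expect_identical(combineScansAndRescale(c(0, 0), Mstar = 5000)$S, 0L)
  expect_error(combineScansAndRescale(c(1, 2), Mstar = 0), "Mstar")
})

test_that("per-subject pipelines keep pair bookkeeping rectangular", {
  set.seed(9)
  prof <- matrix(rnorm(60 * 4), 60, 4,
                 dimnames = list(NULL, c("A", "B", "C", "D")))
  prof[, 3] <- 5                              # degenerate region
  ja <- subjectJointActivation(prof, c = 0.01, T = 100L)
  expect_identical(nrow(ja$Z), 6L)            # choose(4, 2)
  expect_true(all(rowSums(ja$Z) == 100L))
  expect_identical(unname(ja$degenerate), c(FALSE, FALSE, TRUE, FALSE))

  m1 <- matrix(c(0, 30, 10, 0, 0, 80, 50, 20, 0), 3, byrow = TRUE,
               dimnames = list(NULL, c("A", "B", "C")))
  m2 <- matrix(c(0, 10, 30, 40, 0, 0, 10, 60, 0), 3, byrow = TRUE,
               dimnames = list(NULL, c("A", "B", "C")))
  st <- subjectStructuralCounts(list(m1, m2), Mstar = 100, M = 1000L)
  # pair A-B: max(30,0)=30 and max(10,40)=40 -> mean 35 -> scaled 350
  expect_identical(st$S[1], 350L)
  expect_identical(st$pairs[1, ], c("A", "B"))
})
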