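test_that("clustering coefficient matches known graphs and the loop oracle", {
  tri <- makeNetwork(list(c("a", "b"), c("b", "c"), c("a", "c")))
  expect_equal(clusteringCoefficient(tri)$C, 1)
  star <- makeNetwork(list(c("h", "a"), c("h", "b"), c("h", "c")))
  expect_equal(clusteringCoefficient(star)$C, 0)
  cyc3 <- makeNetwork(list(c("a", "b"), c("b", "c"), c("c", "a")),
                      directed = TRUE)
  cc3 <- clusteringCoefficient(cyc3)
  expect_equal(unname(cc3$perNode), rep(0.5, 3))
  expect_equal(cc3$C, 0.5)

  set.seed(31)
  for (r in 1:40) {
    net <- randomNetwork(sample(3:7, 1), sample(2:10, 1),
                         directed = r %% 2 == 0)
    expect_equal(clusteringCoefficient(net)$C, oracleClustering(net),
                 label = sprintf("clustering rep %d", r))
  }
})

test_that("path length matches enumeration and the Floyd-Warshall oracle", {
  k4 <- makeNetwork(list(c("a", "b"), c("a", "c"), c("a", "d"), c("b", "c"),
                         c("b", "d"), c("c", "d")))
  expect_equal(characteristicPathLength(k4), 1)
  path3 <- makeNetwork(list(c("a", "b"), c("b", "c")))
  expect_equal(characteristicPathLength(path3), 4 / 3)
  twoComp <- makeNetwork(list(c("a", "b"), c("c", "d")))
  expect_equal(characteristicPathLength(twoComp), 1)   # unreachable excluded

  set.seed(32)
  for (r in 1:40) {
    net <- randomNetwork(sample(3:7, 1), sample(2:10, 1),
                         directed = r %% 2 == 1)
    oracle <- oraclePathLength(net)
    if (is.na(oracle)) next
    expect_equal(characteristicPathLength(net), oracle,
                 label = sprintf("path length rep %d", r))
  }
})

test_that("null realizations preserve the degree sequence exactly", {
  set.seed(33)
  for (directed in c(FALSE, TRUE)) {
    net <- randomNetwork(8, 14, directed = directed)
    ds <- degSeq(net)
    for (r in 1:25) {
      null <- StructFC:::nullRealization(net)
      expect_identical(degSeq(null), ds)
      expect_true(validObject(null))      # no self-loops or multi-edges
    }
  }
  # a 4-cycle stays 2-regular
  cyc <- makeNetwork(list(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "a")))
  expect_identical(degSeq(StructFC:::nullRealization(cyc))[[1]],
                   sort(setNames(rep(2, 4), c("a", "b", "c", "d"))))
  expect_error(matchedRandomNull(makeNetwork(list(c("a", "b")))), "2 edges")
})

test_that("random null averages are reproducible and sensible", {
  set.seed(34)
  net <- randomNetwork(12, 24)
  n1 <- matchedRandomNull(net, nRealizations = 30L, seed = 7L)
  n2 <- matchedRandomNull(net, nRealizations = 30L, seed = 7L)
  expect_identical(n1$cRandom, n2$cRandom)
  expect_identical(n1$lRandom, n2$lRandom)
  expect_true(n1$cRandom >= 0 && n1$cRandom <= 1)
  expect_gte(n1$lRandom, 1)
})

test_that("small-world index reproduces the published arithmetic", {
  expect_equal(round(smallWorldIndex(0.02, 3.24, 8.04e-4, 4.58), 2), 35.16)
  expect_equal(smallWorldIndex(0.1, 2.5, 0.1, 2.5), 1)
  # scale-consistency in C
  expect_equal(smallWorldIndex(0.04, 3.24, 2 * 8.04e-4, 4.58),
               smallWorldIndex(0.02, 3.24, 8.04e-4, 4.58))
  expect_error(smallWorldIndex(0.1, 2, 0, 3), "positive")
})

test_that("hub thresholds use the population SD with strict inequality", {
  # degrees 5,1,1,1,1,1: mean 1.667, pop SD 1.491, threshold 3.157 -> one hub
  star5 <- makeNetwork(list(c("h", "a"), c("h", "b"), c("h", "c"),
                            c("h", "d"), c("h", "e")))
  hb <- identifyHubs(star5)
  expect_identical(hb$hubs, "h")
  expect_equal(unname(sort(hb$degrees, decreasing = TRUE)[1]), 5)

  # regular graph: SD = 0, no hubs
  cyc <- makeNetwork(list(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "a")))
  expect_length(identifyHubs(cyc)$hubs, 0)

  # directed star, all arrows outward: center drives, nothing is driven
  dstar <- makeNetwork(list(c("h", "a"), c("h", "b"), c("h", "c"),
                            c("h", "d"), c("h", "e")), directed = TRUE)
  dh <- identifyHubs(dstar)
  expect_identical(dh$drivingHubs, "h")
  expect_length(dh$drivenHubs, 0)

  # invariance under node relabelling
  set.seed(35)
  net <- randomNetwork(9, 16)
  perm <- setNames(sample(LETTERS[1:9]), net@nodes)
  relab <- new("BrainNetwork", nodes = unname(perm[net@nodes]),
               edges = data.frame(from = unname(perm[net@edges$from]),
                                  to = unname(perm[net@edges$to]),
                                  stringsAsFactors = FALSE),
               directed = FALSE)
  expect_identical(sort(unname(perm[identifyHubs(net)$hubs])),
                   sort(identifyHubs(relab)$hubs))
})

test_that("networkMetrics assembles all pieces and builds from edge calls", {
  set.seed(36)
  edges <- data.frame(
    region_a = c("a", "a", "b", "c", "d", "a"),
    region_b = c("b", "c", "c", "d", "e", "e"),
    connected = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    direction = c("a->b", "none", "b->a", "a->b", "a->b", "none"),
    stringsAsFactors = FALSE)
  und <- buildBrainNetwork(edges, directed = FALSE)
  expect_identical(nrow(networkEdges(und)), 5L)
  expect_false(isDirected(und))
  dir <- buildBrainNetwork(edges, directed = TRUE)
  expect_identical(nrow(networkEdges(dir)), 4L)
  expect_identical(networkEdges(dir)$from[2], "c")  # b->a orientation flipped

  m <- networkMetrics(und, nNull = 20L, seed = 9L)
  expect_true(all(c("C", "L", "cRandom", "lRandom", "sigma", "hubs") %in%
                  names(m)))
  expect_equal(m$sigma, (m$C / m$cRandom) / (m$L / m$lRandom))
})
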