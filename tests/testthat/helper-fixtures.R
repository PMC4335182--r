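# Shared helpers: independent oracles and fixture builders. Oracles are
# deliberately naive (loops, enumeration) so they stay independent of the
# implementation they check.

rdirichlet_n <- function(n, shape) {
  t(vapply(seq_len(n), function(i) {
    g <- rgamma(length(shape), shape, 1)
    g / sum(g)
  }, numeric(length(shape))))
}

# a PairPosterior whose theta draws cluster tightly around a target
clusteredPosterior <- function(theta, n = 400L, concentration = 5e4,
                               pair = c("a", "b"), seed = 1L) {
  set.seed(seed)
  th <- rdirichlet_n(n, theta * concentration)
  new("PairPosterior", pair = pair, thetaSamples = th,
      piSamples = runif(n, 0.4, 0.6), acceptanceRate = 0.25,
      jumpSdFinal = 0.01,
      settings = chainSettings(nIterations = n, nBurnin = 0L, thin = 1L))
}

makeNetwork <- function(edges, directed = FALSE, nodes = NULL) {
  ed <- data.frame(from = vapply(edges, `[`, "", 1),
                   to = vapply(edges, `[`, "", 2),
                   stringsAsFactors = FALSE)
  if (is.null(nodes)) nodes <- sort(unique(c(ed$from, ed$to)))
  new("BrainNetwork", nodes = nodes, edges = ed, directed = directed)
}

randomNetwork <- function(nNodes, nEdges, directed = FALSE) {
  labels <- letters[seq_len(nNodes)]
  all <- expand.grid(from = labels, to = labels, stringsAsFactors = FALSE)
  all <- all[all$from != all$to, ]
  if (!directed) all <- all[all$from < all$to, ]
  pick <- all[sample(nrow(all), min(nEdges, nrow(all))), ]
  new("BrainNetwork", nodes = labels, edges = pick, directed = directed)
}

# O(n^3) clustering oracle with the union-neighborhood convention
oracleClustering <- function(net) {
  A <- matrix(0L, length(net@nodes), length(net@nodes),
              dimnames = list(net@nodes, net@nodes))
  for (r in seq_len(nrow(net@edges))) {
    A[net@edges$from[r], net@edges$to[r]] <- 1L
    if (!net@directed) A[net@edges$to[r], net@edges$from[r]] <- 1L
  }
  cs <- numeric(nrow(A))
  for (i in seq_len(nrow(A))) {
    nb <- which(A[i, ] == 1L | A[, i] == 1L)
    k <- length(nb)
    if (k < 2) next
    links <- 0L
    for (u in nb) for (v in nb) if (u != v && A[u, v] == 1L) links <- links + 1L
    # undirected A is symmetric so links = 2 E_i, giving 2E/(k(k-1));
    # directed links are counted once, giving E/(k(k-1))
    cs[i] <- links / (k * (k - 1))
  }
  mean(cs)
}

# Floyd-Warshall path-length oracle (reachable ordered pairs)
oraclePathLength <- function(net) {
  n <- length(net@nodes)
  D <- matrix(Inf, n, n, dimnames = list(net@nodes, net@nodes))
  diag(D) <- 0
  for (r in seq_len(nrow(net@edges))) {
    D[net@edges$from[r], net@edges$to[r]] <- 1
    if (!net@directed) D[net@edges$to[r], net@edges$from[r]] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  diag(D) <- Inf
  vals <- D[is.finite(D)]
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

degSeq <- function(net) {
  g <- asIgraph(net)
  if (net@directed)
    list(sort(igraph::degree(g, mode = "out")),
         sort(igraph::degree(g, mode = "in")))
  else list(sort(igraph::degree(g)))
}

# autocorrelation-aware Monte Carlo standard error of a chain mean
mcse <- function(x) {
  n <- length(x)
  rho <- acf(x, lag.max = min(50, n - 1), plot = FALSE)$acf[-1]
  cut <- which(rho < 0.05)[1]
  if (is.na(cut)) cut <- length(rho)
  tau <- 1 + 2 * sum(rho[seq_len(cut)])
  sd(x) * sqrt(max(tau, 1) / n)
}
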