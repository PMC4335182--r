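## Graph construction from edge calls and the topological metrics used to
## characterize the identified networks: clustering coefficient,
## characteristic path length, degree-matched random null, small-world
## index, hubs. igraph supplies shortest paths and degree-preserving
## rewiring; the clustering coefficient is computed directly because the
## directed convention (union neighborhood) is specific.

#' Build a brain network from an edge table
#'
#' Undirected networks connect every pair called connected; directed
#' networks keep only pairs with a called direction, oriented from the
#' ascendant region.
#'
#' @param edgeTable data.frame from [callEdges()] (or any table with
#'   columns \code{region_a}, \code{region_b}, \code{connected},
#'   \code{direction}).
#' @param directed logical (default FALSE).
#' @param nodes optional character vector of node labels; defaults to the
#'   regions incident to at least one retained edge.
#' @return a [BrainNetwork-class].
#' @export
buildBrainNetwork <- function(edgeTable, directed = FALSE, nodes = NULL) {
  et <- edgeTable[edgeTable$connected %in% TRUE, , drop = FALSE]
  if (directed) {
    et <- et[et$direction %in% c("a->b", "b->a"), , drop = FALSE]
    from <- ifelse(et$direction == "a->b", et$region_a, et$region_b)
    to <- ifelse(et$direction == "a->b", et$region_b, et$region_a)
  } else {
    from <- et$region_a
    to <- et$region_b
  }
  if (is.null(nodes)) nodes <- sort(unique(c(from, to)))
  if (!length(nodes)) stop("no edges retained: empty network")
  obj <- new("BrainNetwork", nodes = as.character(nodes),
             edges = data.frame(from = as.character(from),
                                to = as.character(to),
                                stringsAsFactors = FALSE),
             directed = isTRUE(directed))
  validObject(obj)
  obj
}

#' Convert a BrainNetwork to an igraph graph
#'
#' @param network a [BrainNetwork-class].
#' @return an igraph graph with the same nodes, edges and directedness.
#' @export
asIgraph <- function(network) {
  igraph::graph_from_data_frame(network@edges, directed = network@directed,
                                vertices = data.frame(name = network@nodes))
}

adjacencyMatrix <- function(network) {
  n <- length(network@nodes)
  A <- matrix(0L, n, n, dimnames = list(network@nodes, network@nodes))
  ed <- network@edges
  if (nrow(ed)) {
    A[cbind(ed$from, ed$to)] <- 1L
    if (!network@directed) A[cbind(ed$to, ed$from)] <- 1L
  }
  A
}

#' Clustering coefficient
#'
#' Per node \eqn{i}, \eqn{C_i = 2E_i / k_i(k_i-1)} (undirected) or
#' \eqn{C_i = E_i / k_i(k_i-1)} (directed), where \eqn{k_i} is the number
#' of neighbors (the union of in- and out-neighbors in the directed case)
#' and \eqn{E_i} the number of links among them (each directed link
#' counted once). Nodes with fewer than two neighbors contribute
#' \eqn{C_i = 0}. The network value \eqn{C} is the mean over all nodes.
#'
#' @param network a [BrainNetwork-class].
#' @return list with \code{perNode} (named numeric) and \code{C} (mean).
#' @export
clusteringCoefficient <- function(network) {
  A <- adjacencyMatrix(network)
  if (!nrow(network@edges)) stop("empty graph")
  n <- nrow(A)
  U <- (A + t(A)) > 0                 # union neighborhood
  perNode <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(U[i, ])
    k <- length(nb)
    if (k < 2L) next
    links <- sum(A[nb, nb])           # directed links counted once;
    perNode[i] <- links / (k * (k - 1))  # symmetric A counts both, = 2E
  }
  names(perNode) <- rownames(A)
  list(perNode = perNode, C = mean(perNode))
}

#' Characteristic path length
#'
#' Mean shortest-path length over ordered reachable node pairs (edge
#' directions respected in directed networks); unreachable pairs are
#' excluded.
#'
#' @param network a [BrainNetwork-class].
#' @return numeric scalar \eqn{L \ge 1}.
#' @export
characteristicPathLength <- function(network) {
  g <- asIgraph(network)
  d <- igraph::distances(g, mode = "out")
  diag(d) <- Inf
  vals <- d[is.finite(d)]
  if (!length(vals)) stop("no reachable node pairs")
  mean(vals)
}

#' Degree-matched random-network null
#'
#' Generates degree-preserving rewirings of the network (double edge
#' swaps rejecting self-loops and multi-edges; in- and out-degrees
#' preserved when directed) and returns the ensemble means of the
#' clustering coefficient and characteristic path length. Every
#' realization has exactly the degree sequence of the input.
#'
#' @param network a [BrainNetwork-class] with at least 2 edges.
#' @param nRealizations number of random networks (default 1000).
#' @param seed RNG seed (default NA: leave RNG state untouched).
#' @param swapsPerEdge rewiring intensity: successful-swap attempts per
#'   edge (default 10).
#' @return list with \code{cRandom}, \code{lRandom}, \code{C} and \code{L}
#'   vectors across realizations, \code{n} and \code{seed}.
#' @export
matchedRandomNull <- function(network, nRealizations = 1000L,
                              seed = NA_integer_, swapsPerEdge = 10) {
  if (nrow(network@edges) < 2L) stop("need at least 2 edges to rewire")
  if (!is.na(seed)) set.seed(seed)
  g <- asIgraph(network)
  nSwap <- ceiling(swapsPerEdge * igraph::ecount(g))
  Cs <- numeric(nRealizations)
  Ls <- numeric(nRealizations)
  for (r in seq_len(nRealizations)) {
    net <- nullRealization(network, g, nSwap)
    Cs[r] <- clusteringCoefficient(net)$C
    Ls[r] <- characteristicPathLength(net)
  }
  list(cRandom = mean(Cs), lRandom = mean(Ls), C = Cs, L = Ls,
       n = nRealizations, seed = seed)
}

# one degree-preserving rewiring of `network` (g = asIgraph(network))
nullRealization <- function(network, g = asIgraph(network),
                            nSwap = 10 * nrow(network@edges)) {
  gr <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                 niter = nSwap))
  el <- igraph::as_edgelist(gr)
  new("BrainNetwork", nodes = network@nodes,
      edges = data.frame(from = el[, 1], to = el[, 2],
                         stringsAsFactors = FALSE),
      directed = network@directed)
}

#' Small-world index
#'
#' \eqn{\sigma = (C/C_{random}) / (L/L_{random})}; \eqn{\sigma > 1}
#' indicates small-world topology (high clustering with short paths
#' relative to a degree-matched random network).
#'
#' @param C,L clustering coefficient and path length of the network.
#' @param cRandom,lRandom means over the matched random ensemble.
#' @return numeric scalar.
#' @examples
#' smallWorldIndex(0.02, 3.24, 8.04e-4, 4.58)   # 35.16 to printed precision
#' @export
smallWorldIndex <- function(C, L, cRandom, lRandom) {
  if (cRandom <= 0 || lRandom <= 0 || L <= 0)
    stop("denominators must be positive")
  (C / cRandom) / (L / lRandom)
}

popSd <- function(x) sqrt(mean((x - mean(x))^2))

#' Identify network hubs
#'
#' Hubs are nodes whose degree exceeds the network mean degree by more
#' than one standard deviation (population formula over all nodes; strict
#' inequality, so a regular network has no hubs). In directed networks,
#' driving hubs use the out-degree and driven hubs the in-degree.
#'
#' @param network a [BrainNetwork-class].
#' @return list with \code{hubs} (total degree) and, for directed
#'   networks, \code{drivingHubs} and \code{drivenHubs}; plus the degree
#'   vectors used.
#' @export
identifyHubs <- function(network) {
  g <- asIgraph(network)
  d <- igraph::degree(g, mode = "all")
  pick <- function(deg) names(deg)[deg > mean(deg) + popSd(deg)]
  out <- list(hubs = pick(d), degrees = d)
  if (network@directed) {
    dout <- igraph::degree(g, mode = "out")
    din <- igraph::degree(g, mode = "in")
    out$drivingHubs <- pick(dout)
    out$drivenHubs <- pick(din)
    out$outDegrees <- dout
    out$inDegrees <- din
  }
  out
}

#' All topological metrics of a brain network
#'
#' Computes the clustering coefficient, characteristic path length, the
#' degree-matched random-network null, the small-world index and the hub
#' sets.
#'
#' @param network a [BrainNetwork-class].
#' @param nNull random networks in the null ensemble (default 1000).
#' @param seed seed for the null ensemble.
#' @return list with \code{C}, \code{L}, \code{cRandom}, \code{lRandom},
#'   \code{sigma}, \code{hubs}, \code{nNull}, \code{nullSeed} and the
#'   per-node values.
#' @export
networkMetrics <- function(network, nNull = 1000L, seed = NA_integer_) {
  cc <- clusteringCoefficient(network)
  L <- characteristicPathLength(network)
  nul <- matchedRandomNull(network, nRealizations = nNull, seed = seed)
  sig <- smallWorldIndex(cc$C, L, nul$cRandom, nul$lRandom)
  hubs <- identifyHubs(network)
  list(C = cc$C, perNodeClustering = cc$perNode, L = L,
       cRandom = nul$cRandom, lRandom = nul$lRandom, sigma = sig,
       hubs = hubs, nNull = nNull, nullSeed = seed)
}
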