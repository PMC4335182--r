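## Posterior sampling per region pair: Gibbs updates for theta, an embedded
## Metropolis step for pi, burn-in adaptation of the jumping scale, and
## thinning. The inner loop is compiled (src/pair_chain.cpp) and uses R's
## RNG, so set.seed() gives bit-reproducible chains.

rdirichlet1 <- function(shape) {
  g <- stats::rgamma(length(shape), shape = shape, rate = 1)
  g / sum(g)
}

#' One Gibbs draw of \eqn{\theta} from its full conditional
#'
#' @param Zall per-subject counts (N x 4 matrix or 4-vector).
#' @param pi current value of \eqn{\pi}.
#' @param hyper a [ModelHyperparameters-class].
#' @return numeric 4-vector on the simplex.
#' @export
gibbsStepTheta <- function(Zall, pi, hyper = modelHyperparameters()) {
  rdirichlet1(conditionalThetaParams(Zall, pi, hyper))
}

#' One Metropolis update of \eqn{\pi}
#'
#' Proposes \eqn{\pi^* \sim N(\pi, \mathrm{jumpSd}^2)} and accepts with
#' probability \eqn{\min(r, 1)} where \eqn{r} is the ratio of the full
#' conditional densities. Proposals outside (0,1) have zero conditional
#' density and are always rejected.
#'
#' @param pi current value in (0,1).
#' @param jumpSd standard deviation of the Normal jumping distribution.
#' @param theta current \eqn{\theta} 4-vector.
#' @param Sall per-subject structural counts.
#' @param hyper a [ModelHyperparameters-class].
#' @return list with \code{pi} (new value) and \code{accepted} (logical).
#' @export
metropolisStepPi <- function(pi, jumpSd, theta, Sall,
                             hyper = modelHyperparameters()) {
  prop <- stats::rnorm(1, mean = pi, sd = jumpSd)
  if (prop <= 0 || prop >= 1) return(list(pi = pi, accepted = FALSE))
  lr <- logConditionalPi(prop, theta, Sall, hyper) -
        logConditionalPi(pi, theta, Sall, hyper)
  if (is.nan(lr)) return(list(pi = pi, accepted = FALSE))
  if (lr >= 0 || stats::runif(1) < exp(lr))
    list(pi = prop, accepted = TRUE)
  else
    list(pi = pi, accepted = FALSE)
}

defaultJumpSd <- function(Ssum, N, hyper) {
  NM <- N * hyper@M
  p0 <- (Ssum + hyper@alpha0) / (NM + hyper@alpha0 + hyper@beta0)
  p0 <- min(max(p0, 1e-6), 1 - 1e-6)
  # 2.4 x the approximate conjugate posterior sd: near-optimal for a
  # one-dimensional random walk, refined further by burn-in adaptation
  2.4 * sqrt(p0 * (1 - p0) / (NM + hyper@alpha0 + hyper@beta0 + 1))
}

#' Run the Gibbs-with-Metropolis chain for one region pair
#'
#' Samples the joint posterior \eqn{p(\theta, \pi \mid Z, S)}. The jumping
#' scale for \eqn{\pi} is adapted in batches of 50 iterations during
#' burn-in only (vanishing adaptation toward the target acceptance rate),
#' then frozen so the post burn-in chain has the correct stationary
#' distribution. Initialization: \eqn{\pi^0} at its approximate conjugate
#' posterior mean, \eqn{\theta^0} drawn from its full conditional.
#'
#' @param Zall per-subject joint-activation counts (N x 4 matrix or a
#'   4-vector for a single subject).
#' @param Sall per-subject structural counts (length N). \code{NULL}
#'   drops the structural likelihood entirely (flat-prior \eqn{\pi});
#'   see [fitAllPairs()].
#' @param hyper a [ModelHyperparameters-class].
#' @param settings a [ChainSettings-class].
#' @param pair character(2) region labels (metadata only).
#' @return a [PairPosterior-class].
#' @examples
#' sim <- simulatePairDataset(N = 5, seed = 1)
#' pp <- runPairChain(sim$Z, sim$S,
#'                    settings = chainSettings(2000L, 500L, seed = 1L))
#' colMeans(thetaSamples(pp)); mean(piSamples(pp))
#' @export
runPairChain <- function(Zall, Sall, hyper = modelHyperparameters(),
                         settings = chainSettings(),
                         pair = c("a", "b")) {
  Z <- if (is.matrix(Zall)) Zall else matrix(as.numeric(Zall), nrow = 1L)
  if (ncol(Z) != 4L) stop("Zall must have 4 columns")
  if (any(Z < 0)) stop("negative counts")
  noStructural <- is.null(Sall)
  if (noStructural) {
    Sall <- numeric(0)
    N <- nrow(Z)
    NM <- 0
  } else {
    if (length(Sall) != nrow(Z))
      stop("Sall must have one entry per subject (row of Zall)")
    if (any(Sall < 0) || any(Sall > hyper@M)) stop("S must lie in [0, M]")
    N <- nrow(Z)
    NM <- N * hyper@M
  }
  Ssum <- sum(Sall)
  zs <- colSums(Z)
  if (sum(zs) == 0 && NM == 0 && hyper@alpha0 <= 0)
    stop("all-zero data with degenerate hyperparameters")

  if (!is.na(settings@seed)) set.seed(settings@seed)
  jumpSd <- settings@jumpSd
  if (is.na(jumpSd)) {
    jumpSd <- if (NM > 0) defaultJumpSd(Ssum, N, hyper)
              else 2.4 * sqrt(hyper@alpha0 * hyper@beta0 /
                     ((hyper@alpha0 + hyper@beta0)^2 *
                      (hyper@alpha0 + hyper@beta0 + 1)))
  }
  res <- pair_chain_cpp(
    Zsum = as.numeric(zs), Ssum = Ssum, NM = NM,
    alpha0 = hyper@alpha0, beta0 = hyper@beta0, alphas = hyper@alpha,
    fam = linkFamilyCode(hyper@link), par = hyper@link@parameter,
    coef = hyper@link@coef,
    nIter = settings@nIterations, nBurnin = settings@nBurnin,
    thin = settings@thin, jumpSd = jumpSd,
    targetAcc = settings@targetAcceptance, adapt = settings@adapt)
  new("PairPosterior", pair = as.character(pair),
      thetaSamples = res$theta, piSamples = res$pi,
      acceptanceRate = res$acceptance_rate, jumpSdFinal = res$jump_sd,
      settings = settings)
}

pairSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index)) %% 2147483647)
}

#' Fit the model for every region pair
#'
#' Pairs are processed independently; each pair's chain seed is derived
#' deterministically from the base seed and the pair index, so results do
#' not depend on processing order.
#'
#' @param Zlist list of per-pair count matrices (each N x 4).
#' @param Slist list of per-pair structural count vectors (each length N);
#'   entries may be \code{NULL} when \code{missingStructural =
#'   "flat-prior"}.
#' @param pairs character matrix (2 columns) of region labels, one row per
#'   pair; defaults to \code{names(Zlist)} split on \code{"--"} or
#'   generated labels.
#' @param hyper a [ModelHyperparameters-class].
#' @param settings a [ChainSettings-class]; its \code{seed} is the base
#'   seed.
#' @param missingStructural \code{"error"} (default) or
#'   \code{"flat-prior"}: fall back to a flat-prior \eqn{\pi} with a
#'   constant link (no structure-function coupling) for pairs without
#'   structural counts, with a message.
#' @return list of [PairPosterior-class] objects.
#' @export
fitAllPairs <- function(Zlist, Slist, pairs = NULL,
                        hyper = modelHyperparameters(),
                        settings = chainSettings(),
                        missingStructural = c("error", "flat-prior")) {
  missingStructural <- match.arg(missingStructural)
  nPair <- length(Zlist)
  if (length(Slist) != nPair) stop("Zlist and Slist lengths differ")
  if (is.null(pairs)) {
    nm <- names(Zlist)
    pairs <- if (!is.null(nm) && all(grepl("--", nm, fixed = TRUE)))
      do.call(rbind, strsplit(nm, "--", fixed = TRUE))
    else cbind(paste0("R", seq_len(nPair)), paste0("R", seq_len(nPair) + 1L))
  }
  baseSeed <- if (is.na(settings@seed)) 0L else settings@seed
  flatHyper <- NULL
  out <- vector("list", nPair)
  for (k in seq_len(nPair)) {
    s <- settings
    s@seed <- pairSeed(baseSeed, k)
    Sk <- Slist[[k]]
    if (is.null(Sk)) {
      if (missingStructural == "error")
        stop(sprintf("missing structural counts for pair %d (%s--%s)",
                     k, pairs[k, 1], pairs[k, 2]))
      if (is.null(flatHyper)) {
        flatHyper <- hyper
        flatHyper@link <- linkFunction("constant",
                                       targetMean = hyper@link@targetMean)
      }
      message(sprintf("pair %s--%s: no structural counts, flat-prior fallback",
                      pairs[k, 1], pairs[k, 2]))
      out[[k]] <- runPairChain(Zlist[[k]], NULL, flatHyper, s, pairs[k, ])
    } else {
      out[[k]] <- runPairChain(Zlist[[k]], Sk, hyper, s, pairs[k, ])
    }
  }
  names(out) <- paste(pairs[, 1], pairs[, 2], sep = "--")
  out
}
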