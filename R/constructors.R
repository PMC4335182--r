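#' Create a structure-function link function
#'
#' Constructs an increasing link \eqn{\alpha(\pi)} normalized so that its
#' integral over \eqn{[0,1]} equals \code{targetMean}. The default,
#' \code{linkFunction()}, is the exponential link with base 10:
#' \eqn{\alpha(\pi) = C (10^\pi - 1)} with
#' \eqn{C = 10 / (9/\ln 10 - 1) \approx 3.438026}, so that the prior mean
#' of \eqn{\theta_1} rises from \eqn{5/35 \approx 0.14} at \eqn{\pi = 0}
#' to \eqn{\approx 0.55} at \eqn{\pi = 1}.
#'
#' @param family one of \code{"exp-base"}, \code{"power"},
#'   \code{"constant"}.
#' @param parameter base \eqn{b} for \code{"exp-base"} (any positive value
#'   other than 1; bases below 1 give concave increasing links), exponent
#'   \eqn{p > 0} for \code{"power"}; ignored for \code{"constant"}.
#' @param targetMean integral of \eqn{\alpha(\pi)} over \eqn{[0,1]}
#'   (default 10).
#' @return a [LinkFunction-class] object.
#' @examples
#' lk <- linkFunction()            # g(10), the default
#' alphaLink(c(0, 0.5, 1), lk)
#' f15 <- linkFunction("power", 1.5)
#' g001 <- linkFunction("exp-base", 0.01)
#' @export
linkFunction <- function(family = c("exp-base", "power", "constant"),
                         parameter = 10, targetMean = 10) {
  family <- match.arg(family)
  coef <- switch(family,
    "exp-base" = targetMean / ((parameter - 1) / log(parameter) - 1),
    "power"    = targetMean * (parameter + 1),
    "constant" = targetMean)
  obj <- new("LinkFunction", family = family, parameter = as.numeric(parameter),
             targetMean = as.numeric(targetMean), coef = coef)
  validObject(obj)
  obj
}

#' Create model hyperparameters
#'
#' @param alpha0,beta0 Beta prior parameters for the structural-connection
#'   probability \eqn{\pi} (defaults 1, 1).
#' @param alpha1,alpha2,alpha3,alpha4 Dirichlet prior weights for
#'   \eqn{\theta} (defaults 5, 10, 10, 10); the link value
#'   \eqn{\alpha(\pi)} is added to the first cell.
#' @param link a [LinkFunction-class] (default \code{linkFunction()}).
#' @param T scaled number of scans per subject (default 100).
#' @param M scaled number of tractography trials (default 1000).
#' @param c activation threshold in units of the regional standard
#'   deviation (default 0.01).
#' @return a [ModelHyperparameters-class] object.
#' @export
modelHyperparameters <- function(alpha0 = 1, beta0 = 1,
                                 alpha1 = 5, alpha2 = 10, alpha3 = 10,
                                 alpha4 = 10, link = linkFunction(),
                                 T = 100L, M = 1000L, c = 0.01) {
  obj <- new("ModelHyperparameters", alpha0 = as.numeric(alpha0),
             beta0 = as.numeric(beta0),
             alpha = as.numeric(c(alpha1, alpha2, alpha3, alpha4)),
             link = link, T = as.integer(T), M = as.integer(M),
             c = as.numeric(c))
  validObject(obj)
  obj
}

#' Create MCMC chain settings
#'
#' Defaults follow the data-analysis configuration: 10000 retained-phase
#' iterations after 2000 burn-in, thinning by 10, burn-in adaptation of the
#' jumping scale toward 25\% acceptance. Simulation studies use shorter
#' chains (see [runBiasStudy()]).
#'
#' @param nIterations post burn-in iterations.
#' @param nBurnin burn-in iterations.
#' @param thin retain every \code{thin}-th post burn-in state.
#' @param jumpSd initial Normal jumping standard deviation for \eqn{\pi};
#'   \code{NA} chooses \eqn{2.4\,\mathrm{sd}(\pi)} from the approximate
#'   conjugate posterior.
#' @param targetAcceptance acceptance rate targeted during burn-in.
#' @param adapt adapt the jumping scale during burn-in.
#' @param seed RNG seed (\code{NA}: leave RNG state untouched).
#' @return a [ChainSettings-class] object.
#' @export
chainSettings <- function(nIterations = 10000L, nBurnin = 2000L, thin = 10L,
                          jumpSd = NA_real_, targetAcceptance = 0.25,
                          adapt = TRUE, seed = NA_integer_) {
  obj <- new("ChainSettings", nIterations = as.integer(nIterations),
             nBurnin = as.integer(nBurnin), thin = as.integer(thin),
             jumpSd = as.numeric(jumpSd),
             targetAcceptance = as.numeric(targetAcceptance),
             adapt = isTRUE(adapt), seed = as.integer(seed))
  validObject(obj)
  obj
}

#' Create edge-calling thresholds
#'
#' @param eKappa coherence effect size (default 0.4).
#' @param pKappa posterior probability threshold for connection (default 0.5).
#' @param eTau ascendancy effect size; \code{NA} (default) uses the median
#'   orientation-normalized posterior-mean tau across connected pairs.
#' @param pTau posterior probability threshold for direction (default 0.5).
#' @return an [InferenceThresholds-class] object.
#' @export
inferenceThresholds <- function(eKappa = 0.4, pKappa = 0.5,
                                eTau = NA_real_, pTau = 0.5) {
  obj <- new("InferenceThresholds", eKappa = as.numeric(eKappa),
             pKappa = as.numeric(pKappa), eTau = as.numeric(eTau),
             pTau = as.numeric(pTau))
  validObject(obj)
  obj
}

## ---- accessors ------------------------------------------------------------

#' @describeIn PairPosterior-class retained theta draws (matrix, 4 columns).
#' @param object a \code{PairPosterior}.
#' @export
setGeneric("thetaSamples", function(object) standardGeneric("thetaSamples"))

#' @rdname PairPosterior-class
#' @export
setMethod("thetaSamples", "PairPosterior", function(object) object@thetaSamples)

#' @describeIn PairPosterior-class retained pi draws (numeric vector).
#' @export
setGeneric("piSamples", function(object) standardGeneric("piSamples"))

#' @rdname PairPosterior-class
#' @export
setMethod("piSamples", "PairPosterior", function(object) object@piSamples)

#' @describeIn PairPosterior-class post burn-in Metropolis acceptance rate.
#' @export
setGeneric("acceptanceRate", function(object) standardGeneric("acceptanceRate"))

#' @rdname PairPosterior-class
#' @export
setMethod("acceptanceRate", "PairPosterior",
          function(object) object@acceptanceRate)

#' @describeIn BrainNetwork-class node labels.
#' @param object a \code{BrainNetwork}.
#' @export
setGeneric("networkNodes", function(object) standardGeneric("networkNodes"))

#' @rdname BrainNetwork-class
#' @export
setMethod("networkNodes", "BrainNetwork", function(object) object@nodes)

#' @describeIn BrainNetwork-class edge data.frame (columns from, to).
#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))

#' @rdname BrainNetwork-class
#' @export
setMethod("networkEdges", "BrainNetwork", function(object) object@edges)

#' @describeIn BrainNetwork-class whether the network is directed.
#' @export
setGeneric("isDirected", function(object) standardGeneric("isDirected"))

#' @rdname BrainNetwork-class
#' @export
setMethod("isDirected", "BrainNetwork", function(object) object@directed)

## ---- show methods ---------------------------------------------------------

setMethod("show", "LinkFunction", function(object) {
  par <- if (object@family == "constant") ""
         else sprintf("(%g)", object@parameter)
  cat(sprintf("LinkFunction %s%s, target mean %g, coef %.6f\n",
              object@family, par, object@targetMean, object@coef))
})

setMethod("show", "ModelHyperparameters", function(object) {
  cat(sprintf(
    "ModelHyperparameters: Beta(%g, %g) prior on pi; Dirichlet(alpha(pi)+%g, %g, %g, %g) prior on theta\n",
    object@alpha0, object@beta0, object@alpha[1], object@alpha[2],
    object@alpha[3], object@alpha[4]))
  cat(sprintf("  scaling T = %d scans, M = %d trials; threshold c = %g\n",
              object@T, object@M, object@c))
  cat("  link: "); show(object@link)
})

setMethod("show", "ChainSettings", function(object) {
  cat(sprintf(
    "ChainSettings: %d iterations + %d burn-in, thin %d (%d retained); target acceptance %.2f%s\n",
    object@nIterations, object@nBurnin, object@thin,
    object@nIterations %/% object@thin, object@targetAcceptance,
    if (object@adapt) ", burn-in adaptation" else ""))
})

setMethod("show", "PairPosterior", function(object) {
  cat(sprintf("PairPosterior %s -- %s: %d retained samples\n",
              object@pair[1], object@pair[2], length(object@piSamples)))
  cat(sprintf("  posterior means: theta = (%s), pi = %.4f\n",
              paste(sprintf("%.4f", colMeans(object@thetaSamples)),
                    collapse = ", "),
              mean(object@piSamples)))
  cat(sprintf("  acceptance rate %.3f, jumping sd %.4g\n",
              object@acceptanceRate, object@jumpSdFinal))
})

setMethod("show", "InferenceThresholds", function(object) {
  cat(sprintf(
    "InferenceThresholds: e_kappa = %g (p > %g), e_tau = %s (p > %g)\n",
    object@eKappa, object@pKappa,
    if (is.na(object@eTau)) "auto-median" else sprintf("%g", object@eTau),
    object@pTau))
})

setMethod("show", "BrainNetwork", function(object) {
  cat(sprintf("BrainNetwork: %d nodes, %d %s edges\n",
              length(object@nodes), nrow(object@edges),
              if (object@directed) "directed" else "undirected"))
})
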