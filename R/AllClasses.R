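## Central S4 containers. Construction goes through the lower-case
## constructor functions (linkFunction(), modelHyperparameters(), ...);
## validity methods enforce the model's support constraints.

#' Structure-function link function \eqn{\alpha(\pi)}
#'
#' An increasing map from the structural-connection probability \eqn{\pi}
#' to the extra Dirichlet prior weight placed on joint activation
#' (\eqn{\theta_1}). Every admissible link integrates to \code{targetMean}
#' over \eqn{[0,1]} so that different families place the same total prior
#' mass on the structure-function coupling.
#'
#' Families:
#' \describe{
#'   \item{exp-base}{\eqn{g(b)(\pi) = C_b (b^\pi - 1)} with
#'     \eqn{C_b = m / ((b-1)/\ln b - 1)}; the package default is
#'     \eqn{b = 10}, \eqn{m = 10}, giving
#'     \eqn{C \approx 3.438026} and \eqn{\alpha(1) \approx 30.942}.
#'     For \eqn{0 < b < 1} the constant \eqn{C_b} is negative and the
#'     function is still increasing.}
#'   \item{power}{\eqn{f(p)(\pi) = m (p+1) \pi^p}.}
#'   \item{constant}{\eqn{\alpha(\pi) \equiv m}; severs the
#'     structure-function coupling (used by the functional-only comparator
#'     and by conjugate closed-form checks).}
#' }
#'
#' @slot family character, one of \code{"exp-base"}, \code{"power"},
#'   \code{"constant"}.
#' @slot parameter numeric, the base \eqn{b} (exp-base) or exponent \eqn{p}
#'   (power); unused for constant.
#' @slot targetMean numeric, the integral of \eqn{\alpha(\pi)} over
#'   \eqn{[0,1]} (default 10).
#' @slot coef numeric, the normalizing constant implied by the family,
#'   parameter and target mean (stored to full precision).
#' @export
setClass("LinkFunction",
  representation(family = "character", parameter = "numeric",
                 targetMean = "numeric", coef = "numeric"))

setValidity("LinkFunction", function(object) {
  fam <- object@family
  if (length(fam) != 1L || !fam %in% c("exp-base", "power", "constant"))
    return("family must be one of 'exp-base', 'power', 'constant'")
  if (!is.finite(object@targetMean) || object@targetMean <= 0)
    return("targetMean must be a positive number")
  if (fam == "exp-base" &&
      (!is.finite(object@parameter) || object@parameter <= 0 ||
       object@parameter == 1))
    return("exp-base parameter (base b) must be positive and != 1")
  if (fam == "power" && (!is.finite(object@parameter) || object@parameter <= 0))
    return("power parameter (exponent p) must be positive")
  grid <- seq(0, 1, length.out = 201L)
  vals <- alphaLink(grid, object)
  if (any(vals < -1e-12)) return("alpha(pi) must be non-negative on [0,1]")
  if (fam != "constant" && any(diff(vals) <= 0))
    return("alpha(pi) must be strictly increasing on [0,1]")
  int <- stats::integrate(function(p) alphaLink(p, object), 0, 1,
                          rel.tol = 1e-10)$value
  if (abs(int - object@targetMean) > 1e-8)
    return(sprintf("integral of alpha(pi) is %.10f, not targetMean %.10f",
                   int, object@targetMean))
  TRUE
})

#' Model hyperparameters
#'
#' Hyperparameters of the joint Bayesian model: the Beta(\eqn{\alpha_0,
#' \beta_0}) prior on the structural-connection probability \eqn{\pi},
#' the Dirichlet prior weights \eqn{\alpha_1, \ldots, \alpha_4} on the
#' joint-activation probabilities \eqn{\theta} (with the link
#' \eqn{\alpha(\pi)} added to the first cell), the count scaling units
#' \eqn{T} (scans) and \eqn{M} (tractography trials), and the activation
#' threshold multiplier \eqn{c}.
#'
#' @slot alpha0,beta0 numeric, Beta prior parameters for \eqn{\pi}
#'   (defaults 1, 1: flat).
#' @slot alpha numeric length-4 vector \eqn{(\alpha_1, \ldots, \alpha_4)},
#'   defaults (5, 10, 10, 10).
#' @slot link a [LinkFunction-class].
#' @slot T integer, scaled number of scans (default 100).
#' @slot M integer, scaled number of tractography trials (default 1000).
#' @slot c numeric, activation threshold in units of the regional standard
#'   deviation (default 0.01).
#' @export
setClass("ModelHyperparameters",
  representation(alpha0 = "numeric", beta0 = "numeric", alpha = "numeric",
                 link = "LinkFunction", T = "integer", M = "integer",
                 c = "numeric"))

setValidity("ModelHyperparameters", function(object) {
  if (!is.finite(object@alpha0) || object@alpha0 <= 0) return("alpha0 must be > 0")
  if (!is.finite(object@beta0) || object@beta0 <= 0) return("beta0 must be > 0")
  if (length(object@alpha) != 4L || any(!is.finite(object@alpha)) ||
      any(object@alpha <= 0))
    return("alpha must be 4 positive numbers (alpha1..alpha4)")
  if (object@T < 1L) return("T must be >= 1")
  if (object@M < 1L) return("M must be >= 1")
  if (!is.finite(object@c)) return("c must be finite")
  TRUE
})

#' MCMC chain settings
#'
#' @slot nIterations integer, post burn-in iterations (default 10000).
#' @slot nBurnin integer, burn-in iterations (default 2000).
#' @slot thin integer, keep every \code{thin}-th post burn-in state
#'   (default 10).
#' @slot jumpSd numeric, initial standard deviation of the Normal jumping
#'   distribution for \eqn{\pi}; \code{NA} means choose automatically from
#'   the approximate conjugate posterior scale.
#' @slot targetAcceptance numeric, Metropolis acceptance rate targeted by
#'   burn-in adaptation (default 0.25).
#' @slot adapt logical, adapt the jumping scale during burn-in (default
#'   TRUE; the scale is frozen after burn-in either way).
#' @slot seed integer, RNG seed; \code{NA} leaves the RNG state untouched.
#' @export
setClass("ChainSettings",
  representation(nIterations = "integer", nBurnin = "integer",
                 thin = "integer", jumpSd = "numeric",
                 targetAcceptance = "numeric", adapt = "logical",
                 seed = "integer"))

setValidity("ChainSettings", function(object) {
  if (object@nIterations < 1L) return("nIterations must be >= 1")
  if (object@nBurnin < 0L) return("nBurnin must be >= 0")
  if (object@thin < 1L) return("thin must be >= 1")
  if (object@nIterations %% object@thin != 0L)
    return("nIterations must be a multiple of thin")
  if (!is.na(object@jumpSd) && object@jumpSd <= 0)
    return("jumpSd must be > 0 (or NA for automatic)")
  if (object@targetAcceptance <= 0 || object@targetAcceptance >= 1)
    return("targetAcceptance must be in (0,1)")
  TRUE
})

#' Retained posterior samples for one region pair
#'
#' @slot pair character(2), region labels (a, b).
#' @slot thetaSamples numeric matrix, retained draws of \eqn{\theta}
#'   (rows on the simplex, columns \eqn{\theta_1 \ldots \theta_4}).
#' @slot piSamples numeric vector, retained draws of \eqn{\pi}, in (0,1).
#' @slot acceptanceRate numeric, post burn-in Metropolis acceptance rate.
#' @slot jumpSdFinal numeric, jumping scale after burn-in adaptation.
#' @slot settings the [ChainSettings-class] used.
#' @export
setClass("PairPosterior",
  representation(pair = "character", thetaSamples = "matrix",
                 piSamples = "numeric", acceptanceRate = "numeric",
                 jumpSdFinal = "numeric", settings = "ChainSettings"))

setValidity("PairPosterior", function(object) {
  th <- object@thetaSamples
  if (ncol(th) != 4L) return("thetaSamples must have 4 columns")
  if (nrow(th) != length(object@piSamples))
    return("thetaSamples rows and piSamples length differ")
  if (any(th < 0) || any(abs(rowSums(th) - 1) > 1e-8))
    return("thetaSamples rows must lie on the simplex")
  if (any(object@piSamples <= 0) || any(object@piSamples >= 1))
    return("piSamples must lie in (0,1)")
  if (object@acceptanceRate < 0 || object@acceptanceRate > 1)
    return("acceptanceRate must be in [0,1]")
  TRUE
})

#' Edge-calling thresholds
#'
#' @slot eKappa numeric, coherence effect size (default 0.4, moderate
#'   agreement).
#' @slot pKappa numeric, posterior probability threshold for connection
#'   (default 0.5).
#' @slot eTau numeric, ascendancy effect size; \code{NA} means the median
#'   of orientation-normalized posterior-mean tau over connected pairs.
#' @slot pTau numeric, posterior probability threshold for direction
#'   (default 0.5).
#' @export
setClass("InferenceThresholds",
  representation(eKappa = "numeric", pKappa = "numeric",
                 eTau = "numeric", pTau = "numeric"))

setValidity("InferenceThresholds", function(object) {
  if (object@eKappa < 0 || object@eKappa >= 1) return("eKappa must be in [0,1)")
  if (object@pKappa <= 0 || object@pKappa >= 1) return("pKappa must be in (0,1)")
  if (object@pTau <= 0 || object@pTau >= 1) return("pTau must be in (0,1)")
  if (!is.na(object@eTau) && object@eTau <= 0) return("eTau must be > 0")
  TRUE
})

#' A brain network
#'
#' Nodes are region labels; edges are functionally connected region pairs.
#' In a directed network an edge from a to b means region a is ascendant
#' to region b.
#'
#' @slot nodes character, region labels.
#' @slot edges data.frame with columns \code{from}, \code{to}.
#' @slot directed logical.
#' @export
setClass("BrainNetwork",
  representation(nodes = "character", edges = "data.frame",
                 directed = "logical"))

setValidity("BrainNetwork", function(object) {
  ed <- object@edges
  if (!all(c("from", "to") %in% names(ed)))
    return("edges must have columns 'from' and 'to'")
  if (nrow(ed)) {
    if (!all(c(ed$from, ed$to) %in% object@nodes))
      return("edge endpoints must be listed in nodes")
    if (any(ed$from == ed$to)) return("self-loops are not allowed")
    key <- if (object@directed) paste(ed$from, ed$to, sep = "\r")
           else paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to), sep = "\r")
    if (anyDuplicated(key)) return("duplicate edges are not allowed")
  }
  if (anyDuplicated(object@nodes)) return("duplicate node labels")
  TRUE
})
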