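## The probability model: likelihood, priors, the structure-function link
## alpha(pi), and the conditional densities used by the sampler. All
## densities are computed in log space with lgamma; no raw gamma ratios.

linkFamilyCode <- function(link) {
  switch(link@family, "constant" = 0L, "exp-base" = 1L, "power" = 2L)
}

#' Evaluate the structure-function link \eqn{\alpha(\pi)}
#'
#' @param pi numeric vector of structural-connection probabilities in
#'   \[0,1\].
#' @param link a [LinkFunction-class] (default \code{linkFunction()}, the
#'   base-10 exponential link).
#' @return numeric vector, \eqn{\alpha(\pi) \ge 0}.
#' @examples
#' alphaLink(0)      # 0
#' alphaLink(1)      # ~30.942
#' integrate(alphaLink, 0, 1)$value  # 10
#' @export
alphaLink <- function(pi, link = linkFunction()) {
  p <- as.numeric(pi)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("pi must lie in [0,1]")
  switch(link@family,
    "constant" = rep(link@coef, length(p)),
    "exp-base" = link@coef * (link@parameter^p - 1),
    "power"    = link@coef * p^link@parameter)
}

#' Prior mean of \eqn{\theta_1} as a function of \eqn{\pi}
#'
#' \eqn{(\alpha(\pi)+\alpha_1) / (\alpha(\pi)+\alpha_1+\alpha_2+\alpha_3+
#' \alpha_4)}; increasing in \eqn{\pi} whenever the link is increasing,
#' which encodes the modeling assumption that stronger structural
#' connectivity raises the prior expectation of joint activation.
#'
#' @param pi numeric vector in \[0,1\].
#' @param hyper a [ModelHyperparameters-class].
#' @return numeric vector in (0,1).
#' @export
priorMeanTheta1 <- function(pi, hyper = modelHyperparameters()) {
  a <- alphaLink(pi, hyper@link)
  (a + hyper@alpha[1]) / (a + sum(hyper@alpha))
}

sumCounts <- function(Zall) {
  Z <- if (is.matrix(Zall)) Zall else matrix(as.numeric(Zall), nrow = 1L)
  if (ncol(Z) != 4L) stop("Z must have 4 columns")
  if (any(Z < 0)) stop("counts must be non-negative")
  colSums(Z)
}

#' Joint log likelihood of one region pair
#'
#' Multinomial-binomial log likelihood up to an additive constant:
#' \eqn{\sum_i (\sum_n Z_{in}) \log\theta_i + (\sum_n S_n)\log\pi +
#' (NM - \sum_n S_n)\log(1-\pi)}. Cells with \eqn{\theta_i = 0} and a
#' positive count return \code{-Inf} rather than an error.
#'
#' @param Zall numeric matrix of per-subject joint-activation counts
#'   (N rows, 4 columns), or a single 4-vector.
#' @param Sall numeric vector of per-subject structural counts.
#' @param theta numeric 4-vector on the simplex.
#' @param pi numeric scalar in (0,1).
#' @param hyper a [ModelHyperparameters-class] (supplies \eqn{M}).
#' @return numeric scalar (may be \code{-Inf}).
#' @export
pairLogLikelihood <- function(Zall, Sall, theta, pi,
                              hyper = modelHyperparameters()) {
  zs <- sumCounts(Zall)
  Ssum <- sum(Sall)
  N <- length(Sall)
  if (any(theta < 0) || abs(sum(theta) - 1) > 1e-8)
    stop("theta must lie on the simplex")
  if (pi <= 0 || pi >= 1) return(-Inf)
  lt <- ifelse(zs > 0, zs * log(theta), 0)      # 0 * log(0) = 0 convention
  sum(lt) + Ssum * log(pi) + (N * hyper@M - Ssum) * log1p(-pi)
}

#' Log full conditional density of \eqn{\pi} (up to a constant)
#'
#' \deqn{\log\Gamma(\alpha(\pi)+\textstyle\sum_i\alpha_i) -
#'   \log\Gamma(\alpha(\pi)+\alpha_1) + (\sum S_n+\alpha_0-1)\log\pi +
#'   (NM-\sum S_n+\beta_0-1)\log(1-\pi) + \alpha(\pi)\log\theta_1}
#'
#' Returns \code{-Inf} outside (0,1) and when \eqn{\theta_1 = 0} with
#' \eqn{\alpha(\pi) > 0}.
#'
#' @param pi numeric vector of evaluation points.
#' @param theta numeric 4-vector on the simplex (only \eqn{\theta_1} is
#'   used).
#' @param Sall numeric vector of per-subject structural counts.
#' @param hyper a [ModelHyperparameters-class].
#' @return numeric vector of log densities.
#' @export
logConditionalPi <- function(pi, theta, Sall, hyper = modelHyperparameters()) {
  Ssum <- sum(Sall)
  N <- length(Sall)
  NM <- N * hyper@M
  a1 <- hyper@alpha[1]
  asum <- sum(hyper@alpha)
  lt1 <- log(theta[1])
  vapply(as.numeric(pi), function(p) {
    if (p <= 0 || p >= 1) return(-Inf)
    a <- alphaLink(p, hyper@link)
    if (!is.finite(lt1) && a > 0) return(-Inf)
    lgamma(a + asum) - lgamma(a + a1) +
      (Ssum + hyper@alpha0 - 1) * log(p) +
      (NM - Ssum + hyper@beta0 - 1) * log1p(-p) +
      a * lt1
  }, numeric(1))
}

#' Dirichlet parameters of the full conditional of \eqn{\theta}
#'
#' \eqn{(\sum_n Z_{1n}+\alpha(\pi)+\alpha_1,\; \sum_n Z_{2n}+\alpha_2,\;
#' \sum_n Z_{3n}+\alpha_3,\; \sum_n Z_{4n}+\alpha_4)}.
#'
#' @param Zall numeric matrix of per-subject counts (N x 4) or a 4-vector.
#' @param pi numeric scalar in \[0,1\].
#' @param hyper a [ModelHyperparameters-class].
#' @return numeric 4-vector of Dirichlet parameters.
#' @export
conditionalThetaParams <- function(Zall, pi, hyper = modelHyperparameters()) {
  zs <- sumCounts(Zall)
  a <- alphaLink(pi, hyper@link)
  zs + c(a + hyper@alpha[1], hyper@alpha[2], hyper@alpha[3], hyper@alpha[4])
}
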