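## Functional coherence (kappa), ascendancy (tau), exceedance probabilities
## and edge calls. kappa and tau are evaluated per retained posterior draw
## of theta, then summarized -- never from the posterior-mean theta.

#' Functional coherence \eqn{\kappa}
#'
#' Chance-corrected agreement between two regions' activation states:
#' \deqn{\kappa = \frac{\theta_1+\theta_4-E}{1-E} \quad \text{if }
#'   \theta_1\theta_4 > \theta_2\theta_3, \qquad 0 \text{ otherwise},}
#' where \eqn{E = (\theta_1+\theta_2)(\theta_1+\theta_3) +
#' (\theta_3+\theta_4)(\theta_2+\theta_4)} is the expected agreement under
#' independence. \eqn{\kappa \in [0,1]}: 1 at complete coherence
#' (\eqn{\theta_1+\theta_4 = 1}), 0 when agreement does not exceed chance.
#'
#' @param theta numeric 4-vector on the simplex, or a matrix of simplex
#'   rows (e.g. retained posterior draws).
#' @return numeric scalar or vector of \eqn{\kappa} values in \[0,1\].
#' @examples
#' coherenceKappa(c(0.5, 0, 0, 0.5))       # 1
#' coherenceKappa(c(0.4, 0.1, 0.1, 0.4))   # 0.6
#' @export
coherenceKappa <- function(theta) {
  th <- if (is.matrix(theta)) theta else matrix(as.numeric(theta), nrow = 1L)
  if (ncol(th) != 4L) stop("theta must have 4 components")
  if (any(th < 0) || any(abs(rowSums(th) - 1) > 1e-8))
    stop("theta rows must lie on the simplex")
  E <- (th[, 1] + th[, 2]) * (th[, 1] + th[, 3]) +
       (th[, 3] + th[, 4]) * (th[, 2] + th[, 4])
  k <- ifelse(E >= 1, 1, (th[, 1] + th[, 4] - E) / (1 - E))
  out <- ifelse(th[, 1] * th[, 4] > th[, 2] * th[, 3], k, 0)
  if (is.matrix(theta)) out else out[1]
}

#' Ascendancy \eqn{\tau_{ab}}
#'
#' Ratio of the marginal activation odds of region a to region b:
#' \deqn{\tau_{ab} = \frac{(\theta_1+\theta_2)/(\theta_3+\theta_4)}
#'   {(\theta_1+\theta_3)/(\theta_2+\theta_4)}.}
#' \eqn{\tau_{ab} > 1} means a is ascendant to b; swapping the regions
#' (\eqn{\theta_2 \leftrightarrow \theta_3}) gives the reciprocal.
#' Undefined (NA) when any marginal probability is 0 or 1.
#'
#' @param theta numeric 4-vector on the simplex or matrix of simplex rows.
#' @return numeric scalar or vector (positive; NA when undefined).
#' @examples
#' ascendancyTau(c(0.4, 0.2, 0.1, 0.3))    # 1.5
#' @export
ascendancyTau <- function(theta) {
  th <- if (is.matrix(theta)) theta else matrix(as.numeric(theta), nrow = 1L)
  if (ncol(th) != 4L) stop("theta must have 4 components")
  if (any(th < 0) || any(abs(rowSums(th) - 1) > 1e-8))
    stop("theta rows must lie on the simplex")
  ma <- th[, 1] + th[, 2]   # P(A_a = 1)
  mb <- th[, 1] + th[, 3]   # P(A_b = 1)
  out <- ifelse(ma <= 0 | ma >= 1 | mb <= 0 | mb >= 1, NA_real_,
                (ma / (1 - ma)) / (mb / (1 - mb)))
  if (is.matrix(theta)) out else out[1]
}

#' Posterior exceedance probability
#'
#' Fraction of retained posterior samples strictly exceeding a threshold,
#' estimating e.g. \eqn{P(\kappa > e_\kappa \mid Z, S)}.
#'
#' @param samples numeric vector of posterior draws (NAs dropped).
#' @param threshold numeric scalar.
#' @return numeric scalar in \[0,1\].
#' @export
exceedanceProb <- function(samples, threshold) {
  x <- samples[!is.na(samples)]
  if (!length(x)) stop("no non-missing samples")
  mean(x > threshold)
}

#' Posterior summaries of one region pair
#'
#' @param posterior a [PairPosterior-class].
#' @return one-row data.frame with posterior means of \eqn{\kappa},
#'   \eqn{\tau} (oriented a to b) and \eqn{\pi}.
#' @keywords internal
pairSummary <- function(posterior) {
  th <- thetaSamples(posterior)
  ks <- coherenceKappa(th)
  ts <- ascendancyTau(th)
  data.frame(region_a = posterior@pair[1], region_b = posterior@pair[2],
             kappa_mean = mean(ks), tau_mean = mean(ts, na.rm = TRUE),
             pi_mean = mean(piSamples(posterior)),
             stringsAsFactors = FALSE)
}

#' Ascendancy effect size from connected-pair summaries
#'
#' The ascendancy threshold \eqn{e_\tau} is the 50th percentile of the
#' orientation-normalized posterior-mean \eqn{\tau} --
#' \eqn{\max(\bar\tau, 1/\bar\tau)}, so the value does not depend on which
#' region of a pair was stored first -- pooled over the functionally
#' connected pairs (ascendancy is only defined for connected pairs).
#'
#' @param tauMeans numeric vector of posterior-mean \eqn{\tau} values of
#'   the connected pairs (either orientation).
#' @return numeric scalar \eqn{e_\tau \ge 1}.
#' @export
determineETau <- function(tauMeans) {
  x <- tauMeans[!is.na(tauMeans)]
  if (!length(x)) stop("no connected pairs: cannot determine e_tau")
  if (any(x <= 0)) stop("tau means must be positive")
  stats::median(pmax(x, 1 / x))
}

#' Call connected and directed edges from pair posteriors
#'
#' A pair is connected when \eqn{P(\kappa > e_\kappa \mid Z, S) > p_\kappa}.
#' Given connection, direction is assessed on the orientation with
#' posterior-mean \eqn{\tau \ge 1}: that region is ascendant when
#' \eqn{P(\tau > e_\tau \mid Z, S) > p_\tau}. When \code{thresholds@eTau}
#' is \code{NA}, \eqn{e_\tau} is computed from the connected pairs via
#' [determineETau()].
#'
#' @param posteriors list of [PairPosterior-class] objects (e.g. from
#'   [fitAllPairs()]).
#' @param thresholds an [InferenceThresholds-class].
#' @return data.frame with one row per pair: columns \code{region_a},
#'   \code{region_b}, \code{kappa_mean}, \code{p_kappa}, \code{tau_mean},
#'   \code{p_tau}, \code{pi_mean}, \code{connected}, \code{direction}
#'   (\code{"a->b"}, \code{"b->a"} or \code{"none"}), and the \code{e_tau}
#'   used.
#' @export
callEdges <- function(posteriors, thresholds = inferenceThresholds()) {
  if (is(posteriors, "PairPosterior")) posteriors <- list(posteriors)
  n <- length(posteriors)
  kap <- vector("list", n); tau <- vector("list", n)
  summ <- do.call(rbind, lapply(posteriors, pairSummary))
  pK <- numeric(n)
  for (k in seq_len(n)) {
    th <- thetaSamples(posteriors[[k]])
    kap[[k]] <- coherenceKappa(th)
    tau[[k]] <- ascendancyTau(th)
    pK[k] <- exceedanceProb(kap[[k]], thresholds@eKappa)
  }
  connected <- pK > thresholds@pKappa
  eTau <- thresholds@eTau
  if (is.na(eTau)) {
    eTau <- if (any(connected)) determineETau(summ$tau_mean[connected])
            else NA_real_
  }
  pT <- rep(NA_real_, n)
  direction <- rep("none", n)
  for (k in seq_len(n)) {
    if (!connected[k] || is.na(eTau)) next
    forward <- summ$tau_mean[k] >= 1
    ts <- if (forward) tau[[k]] else 1 / tau[[k]]
    pT[k] <- exceedanceProb(ts, eTau)
    if (pT[k] > thresholds@pTau)
      direction[k] <- if (forward) "a->b" else "b->a"
  }
  out <- summ
  out$p_kappa <- pK
  out$p_tau <- pT
  out$connected <- connected
  out$direction <- direction
  out$e_tau <- eTau
  rownames(out) <- NULL
  out[, c("region_a", "region_b", "kappa_mean", "p_kappa", "tau_mean",
          "p_tau", "pi_mean", "connected", "direction", "e_tau")]
}
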