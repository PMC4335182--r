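## Synthetic data from the hierarchical generative process and the three
## simulation studies: the estimator-bias grid, the kappa-correlation
## correspondence, and the link-function sensitivity analysis.

#' Simulate one region pair's data from the generative model
#'
#' Draws \eqn{\pi \sim \mathrm{Beta}(\alpha_0, \beta_0)},
#' \eqn{\theta \mid \pi \sim \mathrm{Dirichlet}(\alpha(\pi)+\alpha_1,
#' \alpha_2, \alpha_3, \alpha_4)}, then per subject
#' \eqn{Z_n \sim \mathrm{Multinomial}(T, \theta)} and
#' \eqn{S_n \sim \mathrm{Binomial}(M, \pi)}.
#'
#' @param hyper a [ModelHyperparameters-class].
#' @param N number of subjects (default 15).
#' @param seed RNG seed (NA: leave RNG state untouched).
#' @param pi,theta optionally fix the true values instead of drawing them.
#' @return list with \code{Z} (N x 4 integer matrix), \code{S} (integer
#'   vector length N), \code{theta}, \code{pi}.
#' @export
simulatePairDataset <- function(hyper = modelHyperparameters(), N = 15L,
                                seed = NA_integer_, pi = NULL, theta = NULL) {
  if (N < 1L) stop("N must be >= 1")
  if (!is.na(seed)) set.seed(seed)
  if (is.null(pi)) pi <- stats::rbeta(1, hyper@alpha0, hyper@beta0)
  if (pi < 0 || pi > 1) stop("pi must lie in [0,1]")
  if (is.null(theta)) {
    shape <- c(alphaLink(pi, hyper@link) + hyper@alpha[1], hyper@alpha[2:4])
    theta <- rdirichlet1(shape)
  }
  Z <- t(stats::rmultinom(N, size = hyper@T, prob = theta))
  S <- stats::rbinom(N, size = hyper@M, prob = pi)
  list(Z = Z, S = S, theta = as.numeric(theta), pi = pi)
}

#' Conjugate posterior of the functional-only comparator
#'
#' The comparator uses the same multinomial likelihood with a
#' \eqn{\pi}-independent Dirichlet prior in which the link is replaced by
#' its average \eqn{\bar\alpha} (the link target mean, default 10), so
#' both methods carry equal total prior mass:
#' \eqn{\mathrm{Dirichlet}(\sum Z_1 + \bar\alpha + \alpha_1,
#' \sum Z_2 + \alpha_2, \sum Z_3 + \alpha_3, \sum Z_4 + \alpha_4)}.
#'
#' @param Zall per-subject counts (N x 4 matrix or 4-vector).
#' @param hyper a [ModelHyperparameters-class].
#' @return numeric 4-vector of posterior Dirichlet parameters.
#' @export
fcOnlyPosterior <- function(Zall, hyper = modelHyperparameters()) {
  zs <- sumCounts(Zall)
  zs + c(hyper@link@targetMean + hyper@alpha[1], hyper@alpha[2:4])
}

studySettings <- function(seed = NA_integer_) {
  chainSettings(nIterations = 2000L, nBurnin = 500L, thin = 10L, seed = seed)
}

fitPosteriorMeans <- function(Z, S, hyper, settings) {
  pp <- runPairChain(Z, S, hyper, settings)
  th <- thetaSamples(pp)
  list(theta = colMeans(th),
       kappa = mean(coherenceKappa(th)),
       tau = mean(ascendancyTau(th), na.rm = TRUE))
}

#' Run the estimator-bias simulation study
#'
#' For each hyperparameter cell \eqn{(\alpha_0, \beta_0)}: draws
#' \code{nPi} values of \eqn{\pi}, \code{nThetaPerPi} values of
#' \eqn{\theta} per \eqn{\pi}, and \code{nDatasetsPerTheta} datasets per
#' \eqn{\theta}; fits the structural-functional sampler (and the
#' functional-only conjugate comparator) to each dataset; and reports the
#' mean absolute deviation of the posterior mean from the truth for
#' \eqn{\theta_1, \ldots, \theta_4}, \eqn{\kappa} and \eqn{\tau}, with its
#' SD across datasets and the Monte-Carlo standard error of the cell mean
#' (computed across the \eqn{\pi} clusters, the top of the replication
#' hierarchy, since datasets sharing a \eqn{(\pi, \theta)} draw are
#' correlated).
#'
#' Sample sizes share common random numbers: each dataset is generated at
#' \code{max(N)} subjects and nested subsets are used for the smaller
#' sample sizes, so bias comparisons across N are paired.
#'
#' The default replication (10 x 5 x 20, chains 2000 + 500) is a
#' scaled-down design; pass \code{nThetaPerPi = 10},
#' \code{nDatasetsPerTheta = 100} and longer chains for the full design.
#'
#' @param grid data.frame with columns \code{alpha0}, \code{beta0}
#'   (default: the six-cell grid (1,100), (2,18), (2,5), (2,2), (5,2),
#'   (18,2)).
#' @param N integer vector of sample sizes (default c(15, 30, 100)).
#' @param hyper base [ModelHyperparameters-class] (its alpha0/beta0 are
#'   overridden per cell).
#' @param settings [ChainSettings-class] for the per-dataset chains.
#' @param nPi,nThetaPerPi,nDatasetsPerTheta replication counts.
#' @param estimators subset of \code{c("fc_with_sc", "fc_only")}.
#' @param seed base seed; all draws and chains derive from it.
#' @return data.frame with columns \code{alpha0}, \code{beta0}, \code{E_pi},
#'   \code{N}, \code{estimator}, \code{parameter}, \code{bias}, \code{sd},
#'   \code{se}, \code{n}.
#' @export
runBiasStudy <- function(grid = data.frame(alpha0 = c(1, 2, 2, 2, 5, 18),
                                           beta0 = c(100, 18, 5, 2, 2, 2)),
                         N = c(15L, 30L, 100L),
                         hyper = modelHyperparameters(),
                         settings = studySettings(),
                         nPi = 10L, nThetaPerPi = 5L,
                         nDatasetsPerTheta = 20L,
                         estimators = c("fc_with_sc", "fc_only"),
                         seed = 1L) {
  estimators <- match.arg(estimators, several.ok = TRUE)
  N <- sort(as.integer(N))
  Nmax <- max(N)
  pars <- c("theta1", "theta2", "theta3", "theta4", "kappa", "tau")
  rows <- list()
  ctr <- 0L
  for (cell in seq_len(nrow(grid))) {
    h <- hyper
    h@alpha0 <- grid$alpha0[cell]
    h@beta0 <- grid$beta0[cell]
    # abs errors: [dataset, parameter, N, estimator]
    nTot <- nPi * nThetaPerPi * nDatasetsPerTheta
    err <- array(NA_real_, c(nTot, length(pars), length(N), length(estimators)),
                 dimnames = list(NULL, pars, N, estimators))
    d <- 0L
    for (ip in seq_len(nPi)) {
      ctr <- ctr + 1L
      set.seed(pairSeed(seed, ctr))
      piTrue <- stats::rbeta(1, h@alpha0, h@beta0)
      for (it in seq_len(nThetaPerPi)) {
        ctr <- ctr + 1L
        set.seed(pairSeed(seed, ctr))
        thetaTrue <- rdirichlet1(c(alphaLink(piTrue, h@link) + h@alpha[1],
                                   h@alpha[2:4]))
        kapTrue <- coherenceKappa(thetaTrue)
        tauTrue <- ascendancyTau(thetaTrue)
        truth <- c(thetaTrue, kapTrue, tauTrue)
        for (id in seq_len(nDatasetsPerTheta)) {
          ctr <- ctr + 1L
          sim <- simulatePairDataset(h, N = Nmax, seed = pairSeed(seed, ctr),
                                     pi = piTrue, theta = thetaTrue)
          d <- d + 1L
          for (iN in seq_along(N)) {
            idx <- seq_len(N[iN])
            Zn <- sim$Z[idx, , drop = FALSE]
            Sn <- sim$S[idx]
            if ("fc_with_sc" %in% estimators) {
              ctr <- ctr + 1L
              s <- settings
              s@seed <- pairSeed(seed, ctr)
              est <- fitPosteriorMeans(Zn, Sn, h, s)
              err[d, , iN, "fc_with_sc"] <-
                abs(c(est$theta, est$kappa, est$tau) - truth)
            }
            if ("fc_only" %in% estimators) {
              pp <- fcOnlyPosterior(Zn, h)
              thHat <- pp / sum(pp)
              err[d, 1:4, iN, "fc_only"] <- abs(thHat - thetaTrue)
            }
          }
        }
      }
    }
    piGroup <- rep(seq_len(nPi), each = nThetaPerPi * nDatasetsPerTheta)
    for (iN in seq_along(N)) for (es in estimators) for (p in pars) {
      e <- err[, p, iN, es]
      if (all(is.na(e))) next
      # datasets are nested in theta draws within pi draws, so the MC
      # standard error of the cell mean is taken across the pi clusters
      gm <- tapply(e, piGroup, mean)
      rows[[length(rows) + 1L]] <- data.frame(
        alpha0 = h@alpha0, beta0 = h@beta0,
        E_pi = h@alpha0 / (h@alpha0 + h@beta0),
        N = N[iN], estimator = es, parameter = p,
        bias = mean(e), sd = stats::sd(e),
        se = stats::sd(gm) / sqrt(length(gm)), n = sum(!is.na(e)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

## ---- bivariate-normal correspondence study --------------------------------

# P(X > h, Y > k) for standard bivariate normal with correlation rho,
# by conditional-Gaussian reduction and adaptive quadrature.
bvnOrthant <- function(h, k, rho) {
  if (abs(rho) < 1e-12) return(pnorm(h, lower.tail = FALSE) *
                               pnorm(k, lower.tail = FALSE))
  s <- sqrt(1 - rho^2)
  stats::integrate(function(x) stats::dnorm(x) *
                     stats::pnorm((rho * x - k) / s),
                   lower = h, upper = Inf, rel.tol = 1e-10)$value
}

#' Solve bivariate-normal parameters matching a joint-activation table
#'
#' Finds thresholds \eqn{c_a, c_b} and correlation \eqn{\rho} of a
#' mean-zero bivariate normal such that dichotomizing at the thresholds
#' reproduces the cell probabilities \eqn{\theta}:
#' \eqn{P(R_a > c_a) = \theta_1+\theta_2}, \eqn{P(R_b > c_b) =
#' \theta_1+\theta_3}, and \eqn{P(R_a > c_a, R_b > c_b) = \theta_1}
#' (solved by monotone root finding on the orthant probability,
#' tolerance 1e-8).
#'
#' @param theta interior simplex 4-vector.
#' @param sigmaA2,sigmaB2 marginal variances (default 0.2).
#' @return list with \code{cA}, \code{cB}, \code{rho}.
#' @examples
#' solveBivariateParams(c(0.3, 0.2, 0.2, 0.3))  # cA = cB = 0, rho ~ 0.309
#' @export
solveBivariateParams <- function(theta, sigmaA2 = 0.2, sigmaB2 = 0.2) {
  th <- as.numeric(theta)
  if (length(th) != 4L || any(th <= 0) || abs(sum(th) - 1) > 1e-8)
    stop("theta must be an interior simplex 4-vector")
  if (sigmaA2 <= 0 || sigmaB2 <= 0) stop("variances must be positive")
  pa <- th[1] + th[2]
  pb <- th[1] + th[3]
  hA <- stats::qnorm(1 - pa)       # standardized thresholds
  hB <- stats::qnorm(1 - pb)
  lo <- max(0, pa + pb - 1)
  hi <- min(pa, pb)
  if (th[1] <= lo + 1e-12 || th[1] >= hi - 1e-12)
    stop("theta is inconsistent with any correlation in (-1, 1)")
  f <- function(r) bvnOrthant(hA, hB, r) - th[1]
  rho <- stats::uniroot(f, lower = -1 + 1e-9, upper = 1 - 1e-9,
                        tol = 1e-10)$root
  list(cA = hA * sqrt(sigmaA2), cB = hB * sqrt(sigmaB2), rho = rho)
}

#' Draw joint-activation targets from the generative model
#'
#' Convenience generator for [kappaRhoStudy()]: draws \eqn{(\pi, \theta)}
#' pairs from each hyperparameter cell of the bias-study grid.
#'
#' @param grid data.frame with columns \code{alpha0}, \code{beta0}.
#' @param nPerCell draws per cell.
#' @param hyper base [ModelHyperparameters-class].
#' @param seed RNG seed.
#' @return list with \code{theta} (matrix, 4 columns) and \code{pi}.
#' @export
simulateThetaTargets <- function(grid = data.frame(alpha0 = c(1, 2, 2, 2, 5, 18),
                                                   beta0 = c(100, 18, 5, 2, 2, 2)),
                                 nPerCell = 5L,
                                 hyper = modelHyperparameters(),
                                 seed = 1L) {
  set.seed(seed)
  th <- matrix(NA_real_, nrow(grid) * nPerCell, 4L)
  pis <- numeric(nrow(grid) * nPerCell)
  r <- 0L
  for (cell in seq_len(nrow(grid))) for (j in seq_len(nPerCell)) {
    r <- r + 1L
    pis[r] <- stats::rbeta(1, grid$alpha0[cell], grid$beta0[cell])
    th[r, ] <- rdirichlet1(c(alphaLink(pis[r], hyper@link) + hyper@alpha[1],
                             hyper@alpha[2:4]))
  }
  list(theta = th, pi = pis)
}

#' Coherence-correlation correspondence study
#'
#' For each target \eqn{\theta}: solves the matching bivariate-normal
#' parameters, simulates per-subject activity series of length
#' \code{Tstar}, estimates the Pearson correlation \eqn{\hat\rho}
#' (averaged across subjects) and the functional coherence
#' \eqn{\hat\kappa} through the full pipeline (dichotomize at the implied
#' thresholds, tabulate, rescale, fit the sampler with simulated
#' structural counts), and returns the paired estimates.
#'
#' @param thetaTargets matrix of interior simplex rows.
#' @param piTrue numeric vector of structural probabilities, one per
#'   target (used to simulate S).
#' @param N subjects per dataset (scalar or vector to compare spreads).
#' @param hyper a [ModelHyperparameters-class].
#' @param settings chain settings (default: study chains 2000 + 500).
#' @param Tstar raw series length (default 483 scans).
#' @param sigma2 marginal variance of the activity series (default 0.2).
#' @param seed base seed.
#' @return data.frame with columns \code{target}, \code{N},
#'   \code{rhoTrue}, \code{kappaTrue}, \code{rhoHat}, \code{kappaHat}.
#' @export
kappaRhoStudy <- function(thetaTargets, piTrue, N = c(15L, 100L),
                          hyper = modelHyperparameters(),
                          settings = studySettings(),
                          Tstar = 483L, sigma2 = 0.2, seed = 1L) {
  th <- as.matrix(thetaTargets)
  if (nrow(th) != length(piTrue)) stop("one piTrue per theta target")
  rows <- list()
  ctr <- 0L
  for (tg in seq_len(nrow(th))) {
    sol <- solveBivariateParams(th[tg, ], sigma2, sigma2)
    kapTrue <- coherenceKappa(th[tg, ])
    for (n in as.integer(N)) {
      ctr <- ctr + 1L
      set.seed(pairSeed(seed, ctr))
      sdv <- sqrt(sigma2)
      Z <- matrix(0L, n, 4L)
      rhoHat <- numeric(n)
      for (s in seq_len(n)) {
        z1 <- stats::rnorm(Tstar)
        z2 <- stats::rnorm(Tstar)
        Ra <- sdv * z1
        Rb <- sdv * (sol$rho * z1 + sqrt(1 - sol$rho^2) * z2)
        A <- as.integer(Ra > sol$cA)
        B <- as.integer(Rb > sol$cB)
        Z[s, ] <- rescaleJointCounts(jointActivationCounts(A, B), T = hyper@T)
        rhoHat[s] <- stats::cor(Ra, Rb)
      }
      S <- stats::rbinom(n, hyper@M, piTrue[tg])
      st <- settings
      st@seed <- pairSeed(seed, 100000L + ctr)
      pp <- runPairChain(Z, S, hyper, st)
      rows[[length(rows) + 1L]] <- data.frame(
        target = tg, N = n, rhoTrue = sol$rho, kappaTrue = kapTrue,
        rhoHat = mean(rhoHat),
        kappaHat = mean(coherenceKappa(thetaSamples(pp))))
    }
  }
  do.call(rbind, rows)
}

## ---- link-function sensitivity study --------------------------------------

#' Default sensitivity-study link families
#'
#' The two exponential links \eqn{g(10)} (convex) and \eqn{g(0.01)}
#' (concave) and the two power links \eqn{f(1.5)} (convex) and
#' \eqn{f(0.5)} (concave), all normalized to integral 10 over \[0,1\].
#'
#' @return named list of [LinkFunction-class] objects.
#' @export
sensitivityLinks <- function() {
  list("g(10)" = linkFunction("exp-base", 10),
       "f(1.5)" = linkFunction("power", 1.5),
       "f(0.5)" = linkFunction("power", 0.5),
       "g(0.01)" = linkFunction("exp-base", 0.01))
}

#' Link-function sensitivity study
#'
#' For each generating link and each fixed true \eqn{\pi}: draws
#' \code{nTheta} values of \eqn{\theta} from the generating prior at that
#' \eqn{\pi}, simulates \code{nDatasets} datasets per \eqn{\theta}, fits
#' the model under each candidate fitting link, and reports -- per
#' \eqn{\theta}, then averaged -- the sum over components of the absolute
#' value of the mean signed bias of the posterior-mean \eqn{\theta_i}
#' across datasets.
#'
#' @param generatingLinks,fittingLinks named lists of
#'   [LinkFunction-class] objects (default [sensitivityLinks()]).
#' @param piValues numeric vector of true \eqn{\pi} values.
#' @param hyper base [ModelHyperparameters-class].
#' @param settings chain settings (default: study chains 2000 + 500).
#' @param nTheta \eqn{\theta} draws per cell (default 10).
#' @param nDatasets datasets per \eqn{\theta} (default 100).
#' @param N subjects per dataset (default 30).
#' @param seed base seed.
#' @return data.frame with columns \code{generating}, \code{pi},
#'   \code{fitting}, \code{bias}, \code{se} (across \eqn{\theta} draws),
#'   \code{nTheta}, \code{nDatasets}.
#' @export
runSensitivityStudy <- function(generatingLinks = sensitivityLinks(),
                                fittingLinks = sensitivityLinks(),
                                piValues = c(0.2045, 0.4626, 0.6894, 0.8987),
                                hyper = modelHyperparameters(),
                                settings = studySettings(),
                                nTheta = 10L, nDatasets = 100L, N = 30L,
                                seed = 1L) {
  rows <- list()
  ctr <- 0L
  for (g in seq_along(generatingLinks)) {
    gl <- generatingLinks[[g]]
    for (p in piValues) {
      shape <- c(alphaLink(p, gl) + hyper@alpha[1], hyper@alpha[2:4])
      # per-theta summed |mean signed bias|, per fitting link
      perTheta <- matrix(NA_real_, nTheta, length(fittingLinks))
      for (it in seq_len(nTheta)) {
        ctr <- ctr + 1L
        set.seed(pairSeed(seed, ctr))
        thetaTrue <- rdirichlet1(shape)
        signedSum <- matrix(0, length(fittingLinks), 4L)
        for (id in seq_len(nDatasets)) {
          ctr <- ctr + 1L
          sim <- simulatePairDataset(hyper, N = N, seed = pairSeed(seed, ctr),
                                     pi = p, theta = thetaTrue)
          for (fl in seq_along(fittingLinks)) {
            h <- hyper
            h@link <- fittingLinks[[fl]]
            ctr <- ctr + 1L
            s <- settings
            s@seed <- pairSeed(seed, ctr)
            pp <- runPairChain(sim$Z, sim$S, h, s)
            signedSum[fl, ] <- signedSum[fl, ] +
              (colMeans(thetaSamples(pp)) - thetaTrue)
          }
        }
        perTheta[it, ] <- rowSums(abs(signedSum / nDatasets))
      }
      for (fl in seq_along(fittingLinks)) {
        rows[[length(rows) + 1L]] <- data.frame(
          generating = names(generatingLinks)[g], pi = p,
          fitting = names(fittingLinks)[fl],
          bias = mean(perTheta[, fl]),
          se = stats::sd(perTheta[, fl]) / sqrt(nTheta),
          nTheta = nTheta, nDatasets = nDatasets,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulation-based calibration of the sampler
#'
#' Draws replicate datasets from the prior predictive, fits the chain to
#' each, and records the rank of the true \eqn{\pi} and \eqn{\theta_1}
#' within their retained posterior samples. If the sampler targets the
#' correct posterior the ranks are uniform on \{0, ..., n_kept\}.
#'
#' @param hyper a [ModelHyperparameters-class].
#' @param N subjects per replicate (default 15).
#' @param nReplicates number of replicates (default 200).
#' @param settings chain settings (default: study chains 2000 + 500).
#' @param seed base seed.
#' @return data.frame with columns \code{rankPi}, \code{rankTheta1},
#'   \code{nKept}.
#' @export
sbcRanks <- function(hyper = modelHyperparameters(), N = 15L,
                     nReplicates = 200L, settings = studySettings(),
                     seed = 1L) {
  rp <- integer(nReplicates); rt <- integer(nReplicates)
  nKept <- settings@nIterations %/% settings@thin
  for (r in seq_len(nReplicates)) {
    sim <- simulatePairDataset(hyper, N = N, seed = pairSeed(seed, 2L * r))
    s <- settings
    s@seed <- pairSeed(seed, 2L * r + 1L)
    pp <- runPairChain(sim$Z, sim$S, hyper, s)
    rp[r] <- sum(piSamples(pp) < sim$pi)
    rt[r] <- sum(thetaSamples(pp)[, 1] < sim$theta[1])
  }
  data.frame(rankPi = rp, rankTheta1 = rt, nKept = nKept)
}
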