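## Converting regional activity profiles and tractography counts into the
## model's sufficient statistics (joint-activation counts Z, structural
## counts S).

#' Extract the dominant temporal profile of a voxel matrix
#'
#' Summarizes a scans-by-voxels matrix by the first singular vector in the
#' time domain: the unit-norm length-\eqn{T^*} vector carrying the most
#' dominant temporal trend across voxels. Since singular vectors are
#' defined only up to sign, the sign is fixed by positive correlation with
#' the across-voxel mean signal (or with \code{referenceMean} if supplied).
#'
#' @param voxelMatrix numeric matrix, rows = scans, columns = voxels.
#' @param referenceMean optional numeric vector (length = number of scans)
#'   used for the sign convention instead of the voxel-mean signal.
#' @return numeric vector of length \code{nrow(voxelMatrix)} (unit norm).
#' @export
extractDominantProfile <- function(voxelMatrix, referenceMean = NULL) {
  x <- as.matrix(voxelMatrix)
  if (ncol(x) < 1L || nrow(x) < 2L)
    stop("voxelMatrix must have at least 1 column and 2 rows")
  if (!all(is.finite(x))) stop("voxelMatrix must be finite")
  if (all(x == 0)) stop("degenerate input: all-zero voxel matrix")
  u <- svd(x, nu = 1L, nv = 0L)$u[, 1L]
  ref <- if (is.null(referenceMean)) rowMeans(x) else as.numeric(referenceMean)
  if (length(ref) != length(u))
    stop("referenceMean length must equal the number of scans")
  s <- sum(u * (ref - mean(ref)))
  if (s == 0) s <- sum(u * ref)      # constant reference: align raw inner product
  if (s < 0) u <- -u
  u
}

#' Dichotomize a regional activity profile
#'
#' Marks scan \eqn{t} as an elevated-activity state when the mean-adjusted
#' signal exceeds \eqn{c} standard deviations:
#' \eqn{A_t = I(y_t - \bar y > c\,\hat\sigma)}. The sample standard
#' deviation (denominator \eqn{T^*-1}) is used. A constant profile yields
#' all-zero indicators flagged as degenerate rather than an error, so pair
#' bookkeeping stays rectangular.
#'
#' @param values numeric vector, the regional profile (length >= 2).
#' @param c threshold multiplier (default 0.01).
#' @return integer 0/1 vector with attributes \code{mean}, \code{sd},
#'   \code{threshold} (\eqn{c\,\hat\sigma}) and \code{degenerate}.
#' @export
dichotomize <- function(values, c = 0.01) {
  v <- as.numeric(values)
  if (length(v) < 2L || any(!is.finite(v))) stop("values must be >= 2 finite numbers")
  m <- mean(v)
  s <- stats::sd(v)
  degenerate <- (s == 0)
  if (degenerate) {
    warning("constant profile: degenerate region, all indicators set to 0")
    bits <- integer(length(v))
  } else {
    bits <- as.integer((v - m) > c * s)
  }
  structure(bits, mean = m, sd = s, threshold = c * s, degenerate = degenerate)
}

#' Joint activation counts for a region pair
#'
#' Cross-tabulates two activation indicator series into the raw
#' 4-category counts \eqn{(Z^*_1, \ldots, Z^*_4)}: both active, a only,
#' b only, neither.
#'
#' @param indA,indB integer 0/1 vectors of equal length (same subject).
#' @return integer 4-vector summing to the series length.
#' @export
jointActivationCounts <- function(indA, indB) {
  a <- as.integer(indA); b <- as.integer(indB)
  if (length(a) != length(b)) stop("indicator lengths differ")
  if (any(!(a %in% 0:1)) || any(!(b %in% 0:1))) stop("indicators must be 0/1")
  c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b))
}

#' Rescale joint activation counts to a common number of scans
#'
#' Standardizes raw counts summing to \eqn{T^*} onto the scaling unit
#' \eqn{T} while keeping integer counts that sum exactly to \eqn{T}
#' (the multinomial model requires integers): largest-remainder
#' allocation, ties broken by lowest cell index.
#'
#' @param raw integer 4-vector (any length is accepted).
#' @param Tstar raw total (default \code{sum(raw)}).
#' @param T target total (default 100).
#' @return integer vector of the same length summing to \code{T}.
#' @export
rescaleJointCounts <- function(raw, Tstar = sum(raw), T = 100L) {
  raw <- as.numeric(raw)
  if (any(raw < 0)) stop("counts must be non-negative")
  if (Tstar <= 0) stop("Tstar must be positive")
  if (abs(sum(raw) - Tstar) > 1e-8) stop("counts must sum to Tstar")
  if (T < 1) stop("T must be >= 1")
  exact <- raw * T / Tstar
  base <- floor(exact)
  rem <- exact - base
  short <- as.integer(round(T - sum(base)))
  if (short > 0) {
    ord <- order(-rem, seq_along(rem))   # largest remainder, lowest index first
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  as.integer(base)
}

#' Aggregate voxel-level tractography counts for a directed region pair
#'
#' Returns the \code{q}-quantile (linear interpolation between order
#' statistics) of the voxel-level stream-success counts, reflecting the
#' strongest anatomical connectivity between the regions. Default
#' \code{q = 0.9}, the 90th percentile.
#'
#' @param voxelCounts numeric vector of voxel-level counts.
#' @param q quantile level in \[0,1\] (default 0.9).
#' @return numeric scalar.
#' @export
aggregateDirectionalCounts <- function(voxelCounts, q = 0.9) {
  x <- as.numeric(voxelCounts)
  if (length(x) == 0L) stop("voxelCounts must be non-empty")
  if (any(!is.finite(x)) || any(x < 0)) stop("voxelCounts must be finite and >= 0")
  unname(stats::quantile(x, probs = q, type = 7))
}

#' Symmetrize the two directional counts of a region pair
#'
#' Structural connectivity is treated as symmetric: the pair count is the
#' maximum of the two directional counts.
#'
#' @param countAB,countBA numeric scalars (counts a-to-b and b-to-a).
#' @return numeric scalar.
#' @export
symmetrizePairCounts <- function(countAB, countBA) {
  if (any(c(countAB, countBA) < 0)) stop("counts must be non-negative")
  pmax(countAB, countBA)
}

#' Combine per-scan structural counts and rescale to M trials
#'
#' Averages the symmetrized pair counts across scans (sessions), then
#' rescales from \eqn{M^*} tractography trials to the scaling unit
#' \eqn{M}, rounding to the nearest integer for the binomial likelihood
#' and clamping to \eqn{[0, M]}.
#'
#' @param countsPerScan numeric vector, one symmetrized count per scan.
#' @param Mstar number of tractography trials per voxel (e.g. 5000).
#' @param M scaled number of trials (default 1000).
#' @return list with \code{Sstar} (mean raw count) and \code{S} (integer
#'   scaled count).
#' @export
combineScansAndRescale <- function(countsPerScan, Mstar, M = 1000L) {
  x <- as.numeric(countsPerScan)
  if (length(x) == 0L) stop("countsPerScan must be non-empty")
  if (Mstar <= 0) stop("Mstar must be positive")
  if (any(x < 0) || any(x > Mstar)) stop("counts must lie in [0, Mstar]")
  Sstar <- mean(x)
  S <- as.integer(min(max(round(Sstar * M / Mstar), 0), M))
  list(Sstar = Sstar, S = S)
}

#' Joint-activation counts for all region pairs of one subject
#'
#' Dichotomizes every column of a scans-by-regions profile matrix and
#' cross-tabulates every region pair, returning scaled counts.
#'
#' @param profiles numeric matrix, rows = scans, columns = regions
#'   (column names are region labels).
#' @param c activation threshold multiplier (default 0.01).
#' @param T scaling unit (default 100).
#' @return list with \code{pairs} (character matrix, 2 columns),
#'   \code{Z} (integer matrix, one row per pair, columns Z1..Z4, summing
#'   to \code{T}) and \code{degenerate} (logical per region).
#' @export
subjectJointActivation <- function(profiles, c = 0.01, T = 100L) {
  x <- as.matrix(profiles)
  if (is.null(colnames(x))) colnames(x) <- paste0("R", seq_len(ncol(x)))
  if (ncol(x) < 2L) stop("need at least two regions")
  degen <- logical(ncol(x))
  ind <- matrix(0L, nrow(x), ncol(x), dimnames = list(NULL, colnames(x)))
  for (j in seq_len(ncol(x))) {
    b <- withCallingHandlers(dichotomize(x[, j], c = c),
                             warning = function(w) invokeRestart("muffleWarning"))
    degen[j] <- attr(b, "degenerate")
    ind[, j] <- as.integer(b)
  }
  pr <- t(utils::combn(colnames(x), 2L))
  Z <- matrix(0L, nrow(pr), 4L,
              dimnames = list(NULL, paste0("Z", 1:4)))
  for (k in seq_len(nrow(pr))) {
    raw <- jointActivationCounts(ind[, pr[k, 1]], ind[, pr[k, 2]])
    Z[k, ] <- rescaleJointCounts(raw, T = T)
  }
  names(degen) <- colnames(x)
  list(pairs = pr, Z = Z, degenerate = degen)
}

#' Structural pair counts from square tractography matrices
#'
#' Takes one square region-by-region count matrix per scan (entries
#' already aggregated to the region level, e.g. 90th-percentile voxel
#' counts), symmetrizes each by the directional maximum, averages across
#' scans and rescales to \code{M} trials.
#'
#' @param scanMatrices list of square numeric matrices with identical
#'   region dimnames, one per scan.
#' @param Mstar tractography trials behind the counts.
#' @param M scaling unit (default 1000).
#' @return list with \code{pairs} (character matrix) and \code{S}
#'   (integer vector of scaled counts, one per pair).
#' @export
subjectStructuralCounts <- function(scanMatrices, Mstar, M = 1000L) {
  if (!length(scanMatrices)) stop("need at least one scan matrix")
  mats <- lapply(scanMatrices, as.matrix)
  regions <- colnames(mats[[1]])
  if (is.null(regions)) regions <- paste0("R", seq_len(ncol(mats[[1]])))
  for (m in mats)
    if (nrow(m) != length(regions) || ncol(m) != length(regions))
      stop("scan matrices must be square with matching dimensions")
  pr <- t(utils::combn(regions, 2L))
  S <- integer(nrow(pr))
  idx <- stats::setNames(seq_along(regions), regions)
  for (k in seq_len(nrow(pr))) {
    i <- idx[pr[k, 1]]; j <- idx[pr[k, 2]]
    perScan <- vapply(mats, function(m) symmetrizePairCounts(m[i, j], m[j, i]),
                      numeric(1))
    S[k] <- combineScansAndRescale(perScan, Mstar = Mstar, M = M)$S
  }
  list(pairs = pr, S = S)
}
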