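#' @include AllClasses.R utils.R
NULL

#' LCMV beamformer spatial filters
#'
#' For each source with lead-field column `l`, the linearly constrained
#' minimum variance weight row is `w = (l' Cr^-1 l)^-1 l' Cr^-1`, where
#' `Cr = C + reg * mean(diag(C)) * I` is the diagonally loaded sensor
#' covariance. The unit-gain constraint `w %*% l == 1` passes the target
#' source undistorted while minimizing output variance from all other
#' sources.
#'
#' @param lf A [ToyLeadField-class].
#' @param cov Sensor covariance matrix (symmetric positive semi-definite).
#' @param reg Diagonal loading as a fraction of the mean sensor variance
#'   (default 0.05).
#' @param covWindow Optional `(start, end)` seconds recorded as metadata.
#' @return A [SpatialFilterSet-class].
#' @export
lcmvFilters <- function(lf, cov, reg = 0.05, covWindow = NULL) {
  stopifnot(is(lf, "ToyLeadField"))
  cov <- as.matrix(cov)
  if (nrow(cov) != ncol(cov) || max(abs(cov - t(cov))) > 1e-8 * max(abs(cov)))
    stop("'cov' must be a symmetric matrix")
  if (nrow(cov) != nrow(lf@gain))
    stop("covariance dimension does not match the sensor count")
  if (any(colSums(abs(lf@gain)) == 0))
    stop("zero lead-field column")
  cr <- cov + reg * mean(diag(cov)) * diag(nrow(cov))
  ci <- tryCatch(solve(cr), error = function(e)
    stop("regularized covariance is singular; increase 'reg'"))
  ns <- ncol(lf@gain)
  w <- matrix(0, ns, nrow(cov))
  for (s in seq_len(ns)) {
    l <- lf@gain[, s]
    lc <- drop(crossprod(l, ci))
    w[s, ] <- lc / drop(lc %*% l)
  }
  new("SpatialFilterSet", weights = w, regularization = reg,
      covWindow = covWindow)
}

#' Sensor covariance pooled over trials and the whole epoch
#'
#' @param x An [EpochedSeries-class].
#' @return Channels x channels covariance matrix.
#' @export
sensorCovariance <- function(x) {
  stopifnot(is(x, "EpochedSeries"))
  d <- dim(x@data)
  flat <- matrix(aperm(x@data, c(3, 1, 2)), nrow = d[1L] * d[3L])
  stats::cov(flat)
}

#' Apply spatial filters and aggregate sources into ROI series
#'
#' Source series are `weights %*% sensors` per trial. Each ROI's series is
#' the sign-aligned average of its member sources: every member is flipped to
#' correlate positively with the ROI's first principal direction before
#' averaging, so anatomically arbitrary lead-field polarities do not cancel.
#' With `aggregate = "pc1"` the first principal component score (scaled to
#' the mean member norm) is returned instead.
#'
#' @param x An [EpochedSeries-class] (channels = sensors).
#' @param filters A [SpatialFilterSet-class] from [lcmvFilters()].
#' @param lf The [ToyLeadField-class] the filters were built from (supplies
#'   the source-to-ROI map).
#' @param aggregate `"sign-mean"` (default) or `"pc1"`.
#' @return A [RoiSeries-class] with one region per ROI in `lf@roiMap`.
#' @export
applyFilters <- function(x, filters, lf, aggregate = c("sign-mean", "pc1")) {
  stopifnot(is(x, "EpochedSeries"), is(filters, "SpatialFilterSet"),
            is(lf, "ToyLeadField"))
  aggregate <- match.arg(aggregate)
  d <- dim(x@data)
  if (ncol(filters@weights) != d[2L])
    stop("channel count does not match filter width")
  rois <- unique(lf@roiMap)
  ns <- nrow(filters@weights)
  src <- array(0, dim = c(d[1L], ns, d[3L]))
  for (tr in seq_len(d[1L]))
    src[tr, , ] <- filters@weights %*% matrix(x@data[tr, , ], nrow = d[2L])
  out <- array(0, dim = c(d[1L], length(rois), d[3L]))
  for (r in seq_along(rois)) {
    members <- which(lf@roiMap == rois[r])
    if (length(members) == 0L) stop("ROI with no member sources: ", rois[r])
    if (length(members) == 1L) {
      out[, r, ] <- src[, members, ]
      next
    }
    ## members x pooled-time matrix across all trials
    M <- matrix(aperm(src[, members, , drop = FALSE], c(2, 1, 3)),
                nrow = length(members))
    Mc <- M - rowMeans(M)
    sv <- svd(Mc, nu = 1, nv = 0)
    score <- drop(crossprod(Mc, sv$u[, 1]))      # pooled PC1 time course
    flips <- vapply(seq_along(members), function(j) {
      s <- sum(Mc[j, ] * score)
      if (s >= 0) 1 else -1
    }, numeric(1))
    if (aggregate == "sign-mean") {
      agg <- colMeans(M * flips)
    } else {
      scale <- mean(sqrt(rowSums(Mc^2)))
      agg <- score / sqrt(sum(score^2)) * scale
    }
    ## overall polarity is arbitrary after alignment; anchor it to the plain
    ## member mean where that mean is informative
    anchor <- sum(agg * colMeans(M))
    if (anchor < 0) agg <- -agg
    out[, r, ] <- matrix(agg, nrow = d[1L])
  }
  roiSeries(out, fs = x@fs, t0 = x@t0, regionLabels = rois)
}

#' Mean source power per ROI
#'
#' The ROI power definition used for spectra: the average over member
#' sources of each source's power, not the power of the averaged series.
#'
#' @inheritParams applyFilters
#' @return Named numeric vector of mean power per ROI.
#' @export
roiPower <- function(x, filters, lf) {
  stopifnot(is(x, "EpochedSeries"))
  d <- dim(x@data)
  rois <- unique(lf@roiMap)
  pow <- numeric(ncol(lf@gain))
  for (tr in seq_len(d[1L])) {
    s <- filters@weights %*% matrix(x@data[tr, , ], nrow = d[2L])
    pow <- pow + rowMeans(s^2) / d[1L]
  }
  vapply(rois, function(r) mean(pow[lf@roiMap == r]), numeric(1))
}

#' Multivariate symmetric orthogonalization
#'
#' Finds the set of mutually uncorrelated region series closest in total
#' squared error to the input, removing zero-lag correlations induced by
#' spatial leakage without privileging any region. The demeaned pooled
#' (time x regions) matrix is factored as `U diag(d)` with orthonormal `U`,
#' alternating the closest-orthonormal-matrix step (polar decomposition via
#' SVD) with per-region least-squares rescaling until the relative objective
#' change falls below `tol`. Region means are restored afterwards, so output
#' zero-lag Pearson correlations are < 1e-8 and the map is idempotent.
#'
#' @param roi A [RoiSeries-class]; pooled samples must be at least the number
#'   of regions and region series must be linearly independent.
#' @param tol Relative objective-change convergence tolerance (default 1e-9).
#' @param maxIter Maximum alternation count (default 100).
#' @return A [RoiSeries-class] with mutually uncorrelated region series.
#' @export
symmetricOrthogonalize <- function(roi, tol = 1e-9, maxIter = 100) {
  stopifnot(is(roi, "RoiSeries"))
  d <- dim(roi@data)
  nr <- d[2L]
  ## pooled time x regions matrix
  X <- t(matrix(aperm(roi@data, c(2, 1, 3)), nrow = nr))
  if (nrow(X) < nr)
    stop("pooled samples (", nrow(X), ") fewer than regions (", nr, ")")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  if (qr(Xc)$rank < nr) {
    cc <- abs(cor(Xc)); diag(cc) <- 0
    pair <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
    stop("rank-deficient input: regions '", roi@regionLabels[pair[1L]],
         "' and '", roi@regionLabels[pair[2L]], "' are collinear")
  }
  Y <- .closestOrthogonal(Xc, tol, maxIter)
  Y <- sweep(Y, 2, mu, "+")
  out <- roi
  out@data <- aperm(array(t(Y), dim = c(nr, d[1L], d[3L])), c(2, 1, 3))
  out
}

## Alternating minimization of ||X - U diag(d)||_F with U'U = I.
.closestOrthogonal <- function(X, tol = 1e-9, maxIter = 100) {
  d <- sqrt(colSums(X^2))
  obj <- Inf
  for (it in seq_len(maxIter)) {
    s <- svd(sweep(X, 2, d, "*"))
    U <- s$u %*% t(s$v)
    d <- colSums(U * X)                      # per-column least-squares scale
    newObj <- sum((X - sweep(U, 2, d, "*"))^2)
    if (is.finite(obj) && abs(obj - newObj) <= tol * max(obj, 1e-300)) {
      obj <- newObj
      break
    }
    obj <- newObj
  }
  sweep(U, 2, d, "*")
}
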