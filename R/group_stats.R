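#' @include AllClasses.R utils.R
NULL

## Vectorized one-way fixed-effects F over columns of a subjects x bins
## matrix split into groups (list of matrices with identical bin count).
.onewayF <- function(groups) {
  k <- length(groups)
  ns <- vapply(groups, nrow, integer(1))
  N <- sum(ns)
  gm <- Reduce("+", lapply(groups, colSums)) / N
  means <- lapply(groups, colMeans)
  ssb <- Reduce("+", Map(function(m, n) n * (m - gm)^2, means, ns))
  ssw <- Reduce("+", Map(function(g, m) colSums(sweep(g, 2, m)^2),
                         groups, means))
  dfb <- k - 1
  dfw <- N - k
  f <- (ssb / dfb) / (ssw / dfw)
  list(f = f, p = pf(f, dfb, dfw, lower.tail = FALSE), dfb = dfb, dfw = dfw,
       ssw = ssw)
}

#' Pointwise F test with FDR correction across time bins
#'
#' One-way fixed-effects F between the three groups at every time bin of a
#' band-power time course, followed by Benjamini-Hochberg correction at
#' level `q` across bins. Bins with zero within-group variance (F undefined)
#' are flagged and excluded from the FDR family.
#'
#' @param groups List of 3 subjects x time-bins matrices (non-responder,
#'   responder, HC), identical time grids, >= 2 subjects each.
#' @param q FDR level (default 0.05).
#' @return List: `F`, `p` (raw), `pAdj`, `mask` (logical, BH-surviving bins),
#'   `flagged` (logical, excluded undefined bins).
#' @export
pointwiseFFdr <- function(groups, q = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2)
  nb <- unique(vapply(groups, ncol, integer(1)))
  if (length(nb) != 1) stop("groups must share one time grid")
  if (any(vapply(groups, nrow, integer(1)) < 2))
    stop("need >= 2 subjects per group")
  res <- .onewayF(groups)
  flagged <- !is.finite(res$f) | res$ssw == 0
  p <- res$p
  pAdj <- rep(NA_real_, nb)
  pAdj[!flagged] <- p.adjust(p[!flagged], method = "BH")
  mask <- !is.na(pAdj) & pAdj <= q
  list(F = res$f, p = p, pAdj = pAdj, mask = mask, flagged = flagged)
}

## Pooled-variance two-sample t for columns of subjects x bins matrices.
.tmapTwoSample <- function(A, B) {
  nA <- nrow(A); nB <- nrow(B)
  mA <- colMeans(A); mB <- colMeans(B)
  vA <- colSums(sweep(A, 2, mA)^2)
  vB <- colSums(sweep(B, 2, mB)^2)
  sp <- sqrt((vA + vB) / (nA + nB - 2))
  (mA - mB) / (sp * sqrt(1 / nA + 1 / nB))
}

#' Post-hoc two-sample t tests on surviving bins
#'
#' Student pooled-variance t per retained time bin, responder vs
#' non-responder style contrasts after the omnibus F.
#'
#' @param groupA,groupB Subjects x bins matrices (>= 2 rows each).
#' @param mask Logical or integer selection of bins to test (default all).
#' @return Data frame: `bin`, `t`, `p` (two-sided).
#' @export
posthocT <- function(groupA, groupB, mask = NULL) {
  groupA <- as.matrix(groupA); groupB <- as.matrix(groupB)
  if (nrow(groupA) < 2 || nrow(groupB) < 2)
    stop("group size < 2")
  bins <- seq_len(ncol(groupA))
  if (!is.null(mask)) bins <- bins[mask]
  if (length(bins) == 0) stop("empty bin mask")
  t <- .tmapTwoSample(groupA[, bins, drop = FALSE],
                      groupB[, bins, drop = FALSE])
  df <- nrow(groupA) + nrow(groupB) - 2
  data.frame(bin = bins, t = t, p = 2 * pt(abs(t), df, lower.tail = FALSE))
}

#' Cluster-based permutation test on comodulogram maps
#'
#' Per-bin pooled two-sample t (A - B); bins exceeding the two-sided
#' `clusterAlpha` critical value form clusters under 4-connectivity,
#' separately by sign; the cluster statistic is the mass (sum of t). The
#' null distribution is the maximum absolute cluster mass over the map for
#' each of `P` random relabelings of the pooled subjects, and each observed
#' cluster's p-value is `(1 + #{null >= |mass|}) / (1 + P)` (the observed
#' labeling counts, so p >= 1/(P+1)).
#'
#' @param groupA,groupB Lists of [Comodulogram-class] (identical grids), or
#'   subjects x phase x amp arrays.
#' @param P Number of permutations (default 1000).
#' @param clusterAlpha Two-sided cluster-forming alpha (default 0.05).
#' @param connectivity 4 (default) or 8.
#' @param seed RNG seed for the shuffles.
#' @return A [ClusterTestResult-class].
#' @export
clusterPermutation <- function(groupA, groupB, P = 1000, clusterAlpha = 0.05,
                               connectivity = 4, seed = 1) {
  if (P < 1) stop("P must be >= 1")
  A <- .comodArray(groupA)
  B <- .comodArray(groupB)
  if (!identical(dim(A)[-1L], dim(B)[-1L]))
    stop("comodulogram grids differ between groups")
  np <- dim(A)[2L]; na <- dim(A)[3L]
  if (dim(A)[1L] < 2 || dim(B)[1L] < 2) stop("need >= 2 subjects per group")
  pgrid <- attr(A, "phaseFreqs") %||% seq_len(np)
  agrid <- attr(A, "ampFreqs") %||% seq_len(na)
  XA <- matrix(A, nrow = dim(A)[1L])
  XB <- matrix(B, nrow = dim(B)[1L])
  nA <- nrow(XA); nB <- nrow(XB)
  tcrit <- qt(1 - clusterAlpha / 2, nA + nB - 2)

  tobs <- .tmapTwoSample(XA, XB)
  obs <- .extractClusters(matrix(tobs, np, na), tcrit, connectivity)

  X <- rbind(XA, XB)
  nullMax <- localSeed(seed, vapply(seq_len(P), function(i) {
    idx <- sample.int(nA + nB)
    tp <- .tmapTwoSample(X[idx[seq_len(nA)], , drop = FALSE],
                         X[idx[(nA + 1):(nA + nB)], , drop = FALSE])
    cl <- .extractClusters(matrix(tp, np, na), tcrit, connectivity)
    if (length(cl$masses)) max(abs(cl$masses)) else 0
  }, numeric(1)))

  pvals <- vapply(obs$masses, function(m)
    (1 + sum(nullMax >= abs(m))) / (1 + P), numeric(1))
  new("ClusterTestResult", statMap = matrix(tobs, np, na),
      clusterMasks = obs$masks, clusterMasses = obs$masses,
      clusterSigns = obs$signs, nullMaxMasses = nullMax,
      pValues = pvals, clusterAlpha = clusterAlpha,
      phaseFreqs = as.numeric(pgrid), ampFreqs = as.numeric(agrid))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Coerce a list of Comodulogram (or an array) to subjects x phase x amp.
.comodArray <- function(x) {
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  stopifnot(is.list(x), all(vapply(x, is, logical(1), "Comodulogram")))
  np <- length(x[[1]]@phaseFreqs); na <- length(x[[1]]@ampFreqs)
  arr <- array(NA_real_, dim = c(length(x), np, na))
  for (i in seq_along(x)) {
    if (!identical(x[[i]]@phaseFreqs, x[[1]]@phaseFreqs) ||
        !identical(x[[i]]@ampFreqs, x[[1]]@ampFreqs))
      stop("comodulogram grids differ between subjects")
    arr[i, , ] <- x[[i]]@values
  }
  attr(arr, "phaseFreqs") <- x[[1]]@phaseFreqs
  attr(arr, "ampFreqs") <- x[[1]]@ampFreqs
  arr
}

## Suprathreshold clusters by sign; masses = sum of t over each cluster.
.extractClusters <- function(tmap, tcrit, connectivity = 4) {
  masks <- list(); masses <- numeric(); signs <- character()
  for (sgn in c(1, -1)) {
    m <- if (sgn > 0) tmap > tcrit else tmap < -tcrit
    if (!any(m)) next
    lab <- connectedComponents(m, connectivity)
    for (id in seq_len(max(lab))) {
      idx <- which(lab == id)
      masks[[length(masks) + 1L]] <- idx
      masses <- c(masses, sum(tmap[idx]))
      signs <- c(signs, if (sgn > 0) "positive" else "negative")
    }
  }
  list(masks = masks, masses = masses, signs = signs)
}

#' Per-subject mean coupling strength over a cluster
#'
#' Averages a subject's comodulogram over the bins of a cluster mask; the
#' per-subject feature carried into correlation and ROC analyses.
#'
#' @param subjectComod A [Comodulogram-class] (or plain matrix on the same
#'   grid).
#' @param mask Integer bin indices (as stored in
#'   [ClusterTestResult-class]`@clusterMasks`) or a logical matrix.
#' @return Scalar mean coupling value.
#' @export
clusterMeanStrength <- function(subjectComod, mask) {
  v <- if (is(subjectComod, "Comodulogram")) subjectComod@values
       else as.matrix(subjectComod)
  if (is.logical(mask)) mask <- which(mask)
  if (length(mask) == 0) stop("empty cluster mask")
  if (max(mask) > length(v)) stop("mask outside the comodulogram grid")
  mean(v[mask])
}

#' One-way ANOVA from summary statistics
#'
#' Fixed-effects one-way ANOVA computed from per-group mean, SD and n; equal
#' to the raw-data ANOVA exactly when the summaries come from the raw data.
#'
#' @param means,sds,ns Per-group summary vectors.
#' @return List: `F`, `df`, `p`.
#' @export
anovaFromSummary <- function(means, sds, ns) {
  stopifnot(length(means) == length(sds), length(sds) == length(ns),
            length(means) >= 2)
  N <- sum(ns)
  gm <- sum(ns * means) / N
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((ns - 1) * sds^2)
  dfb <- length(means) - 1
  dfw <- N - length(means)
  f <- (ssb / dfb) / (ssw / dfw)
  list(F = f, df = c(dfb, dfw), p = pf(f, dfb, dfw, lower.tail = FALSE))
}
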