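#' @include AllClasses.R utils.R
NULL

#' Default amplitude-band half-width for envelope extraction
#'
#' The envelope band around an amplitude frequency must be wide enough to
#' pass the modulation sidebands at `f_a +- f_p`, or injected coupling is
#' filtered out by construction: half-width = `max(2, 1.2 * max(phaseFreqs))`
#' Hz (15.6 Hz for the default 8--13 Hz phase grid).
#'
#' @param phaseFreqs Phase-frequency grid in Hz.
#' @return Half-width in Hz.
#' @export
ampHalfWidth <- function(phaseFreqs = 8:13) max(2, 1.2 * max(phaseFreqs))

#' Instantaneous phase or envelope of a band-limited component
#'
#' Band-passes the full epoch around `fCentre` (FFT-domain raised-cosine
#' band mask) and takes the analytic signal over the full epoch in the same
#' transform, avoiding window-edge distortion; any analysis windowing happens
#' downstream. Phase bands are `fCentre +- 1` Hz; amplitude bands use
#' [ampHalfWidth()].
#'
#' @param roi A [RoiSeries-class].
#' @param region Region label.
#' @param fCentre Band center in Hz.
#' @param kind `"phase"` or `"envelope"`.
#' @param halfWidth Band half-width in Hz; defaults to 1 for phase and
#'   `ampHalfWidth()` for envelope.
#' @return Trials x samples matrix of instantaneous phase (radians) or
#'   envelope magnitude.
#' @export
phaseEnvelope <- function(roi, region, fCentre, kind = c("phase", "envelope"),
                          halfWidth = NULL) {
  stopifnot(is(roi, "RoiSeries"))
  kind <- match.arg(kind)
  if (is.null(halfWidth))
    halfWidth <- if (kind == "phase") 1 else ampHalfWidth()
  if (fCentre - halfWidth <= 0)
    stop("band collapses: ", fCentre, " - ", halfWidth, " Hz <= 0")
  r <- match(region, seriesLabels(roi))
  if (is.na(r)) stop("unknown region: ", region)
  X <- t(matrix(roi@data[, r, ], nrow = dim(roi@data)[1L]))  # samples x trials
  Z <- bandAnalytic(X, roi@fs, fCentre - halfWidth, fCentre + halfWidth)
  out <- if (kind == "phase") Arg(Z) else Mod(Z)
  t(out)
}

#' Phasor-envelope coupling coherence
#'
#' Coherence between the unit phasor of the slow phase and the fast
#' envelope, pooled over window samples and trials:
#' `|sum(env * exp(-1i * phase))| / sqrt(N * sum(env^2))`.
#' Bounded in [0, 1] by Cauchy-Schwarz; invariant to constant phase
#' rotations and to envelope rescaling; 0 for an identically zero envelope
#' by convention. With `estimator = "mvl"` the normalized mean-vector-length
#' variant `|mean(env * exp(-1i * phase))| / mean(env)` is returned instead
#' (a cross-check statistic, also in [0, 1] for non-negative envelopes).
#'
#' @param phase Trials x window-samples matrix of phases (radians).
#' @param env Trials x window-samples matrix of envelopes (same shape).
#' @param estimator `"coherence"` (default) or `"mvl"`.
#' @return Scalar in [0, 1].
#' @export
pacCoherence <- function(phase, env, estimator = c("coherence", "mvl")) {
  estimator <- match.arg(estimator)
  phase <- as.matrix(phase); env <- as.matrix(env)
  if (!all(dim(phase) == dim(env))) stop("phase/envelope length mismatch")
  if (nrow(phase) < 2 && length(phase) < 2) stop("window too small")
  n <- length(env)
  if (estimator == "coherence") {
    den <- sqrt(n * sum(env^2))
    if (den == 0) return(0)
    Mod(sum(env * exp(-1i * phase))) / den
  } else {
    den <- mean(env)
    if (den == 0) return(0)
    Mod(mean(env * exp(-1i * phase))) / den
  }
}

#' Cross-regional phase-amplitude comodulogram
#'
#' For every (phase frequency, amplitude frequency) pair, extracts the slow
#' phase from `phaseRegion` and the fast envelope from `ampRegion` over the
#' full epoch, restricts both to the analysis window, and fills in the pooled
#' [pacCoherence()]. The two pathway windows of interest are 0--50 ms
#' (thalamic, half an alpha cycle) and 100--200 ms (orbitofrontal) after
#' stimulus onset.
#'
#' @param roi A [RoiSeries-class].
#' @param phaseRegion,ampRegion ROI labels; the statistic is asymmetric in
#'   the two roles.
#' @param window `c(tStart, tEnd)` seconds after stimulus onset.
#' @param phaseFreqs Phase grid (default 8--13 Hz, 1-Hz step).
#' @param ampFreqs Amplitude grid (default 30--100 Hz, 1-Hz step).
#' @param halfWidth Amplitude band half-width; default [ampHalfWidth()] of
#'   the phase grid.
#' @param estimator Passed to [pacCoherence()].
#' @return A [Comodulogram-class].
#' @export
comodulogram <- function(roi, phaseRegion, ampRegion, window,
                         phaseFreqs = 8:13, ampFreqs = 30:100,
                         halfWidth = NULL,
                         estimator = c("coherence", "mvl")) {
  stopifnot(is(roi, "RoiSeries"))
  estimator <- match.arg(estimator)
  if (length(phaseFreqs) == 0 || length(ampFreqs) == 0)
    stop("empty frequency grid")
  if (is.null(halfWidth)) halfWidth <- ampHalfWidth(phaseFreqs)
  tAx <- timeAxis(roi)
  wIdx <- which(tAx >= window[1] & tAx <= window[2])
  if (length(wIdx) < 2) stop("window shorter than 2 samples")
  fs <- roi@fs
  nt <- dim(roi@data)[1L]
  pIdx <- match(phaseRegion, seriesLabels(roi))
  aIdx <- match(ampRegion, seriesLabels(roi))
  if (is.na(pIdx)) stop("unknown region: ", phaseRegion)
  if (is.na(aIdx)) stop("unknown region: ", ampRegion)

  Xp <- t(matrix(roi@data[, pIdx, ], nrow = nt))   # samples x trials
  Xa <- t(matrix(roi@data[, aIdx, ], nrow = nt))
  Fp <- .epochSpectrum(Xp)
  Fa <- .epochSpectrum(Xa)

  nw <- length(wIdx) * nt
  ## phasors: nPhase x pooled-window-samples (conjugated for the inner product)
  P <- matrix(0i, length(phaseFreqs), nw)
  for (i in seq_along(phaseFreqs)) {
    Z <- .bandAnalyticFromSpectrum(Fp, fs, phaseFreqs[i] - 1,
                                   phaseFreqs[i] + 1, tw = 0.5)
    ph <- Arg(Z[wIdx, , drop = FALSE])
    P[i, ] <- exp(-1i * as.vector(ph))
  }
  E <- matrix(0, length(ampFreqs), nw)
  for (j in seq_along(ampFreqs)) {
    Z <- .bandAnalyticFromSpectrum(Fa, fs, ampFreqs[j] - halfWidth,
                                   ampFreqs[j] + halfWidth, tw = 2)
    E[j, ] <- as.vector(Mod(Z[wIdx, , drop = FALSE]))
  }

  if (estimator == "coherence") {
    num <- Mod(P %*% t(E))                        # nPhase x nAmp
    den <- sqrt(nw * rowSums(E^2))
    vals <- sweep(num, 2, den, "/")
    vals[, den == 0] <- 0
  } else {
    num <- Mod(P %*% t(E)) / nw
    den <- rowMeans(E)
    vals <- sweep(num, 2, den, "/")
    vals[, den == 0] <- 0
  }
  vals <- pmin(pmax(vals, 0), 1)
  new("Comodulogram", values = vals, phaseFreqs = as.numeric(phaseFreqs),
      ampFreqs = as.numeric(ampFreqs), window = as.numeric(window),
      phaseRegion = phaseRegion, ampRegion = ampRegion,
      nTrialsUsed = as.integer(nt))
}

#' Comodulograms for the two dual-pathway windows
#'
#' Convenience wrapper computing the thalamic (0--50 ms) and orbitofrontal
#' (100--200 ms) cross-regional comodulograms for one subject.
#'
#' @param roi A [RoiSeries-class].
#' @param pairs Data frame like `simulationConfig()$couplingWindows`
#'   (columns `phaseRegion`, `ampRegion`, `tStart`, `tEnd`).
#' @param ... Passed to [comodulogram()].
#' @return Named list of [Comodulogram-class] (names
#'   `"<phase>:<amp>@<t1>-<t2>"`).
#' @export
pathwayComodulograms <- function(roi,
                                 pairs = data.frame(
                                   phaseRegion = c("rTHA", "rOFC"),
                                   ampRegion = c("rAMG", "rAMG"),
                                   tStart = c(0.0, 0.1),
                                   tEnd = c(0.05, 0.2)), ...) {
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    out[[i]] <- comodulogram(roi, pairs$phaseRegion[i], pairs$ampRegion[i],
                             c(pairs$tStart[i], pairs$tEnd[i]), ...)
    names(out)[i] <- sprintf("%s:%s@%g-%g", pairs$phaseRegion[i],
                             pairs$ampRegion[i], pairs$tStart[i],
                             pairs$tEnd[i])
  }
  out
}
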