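#' @include AllClasses.R utils.R
NULL

## Tapered sliding-window power at one frequency for all regions/trials.
## taper: window samples; returns regions x nTimes matrix of trial-averaged
## one-sided PSD estimates (NA where the window does not fit).
.slidingPower <- function(dat, fs, t0, f, centers, tapers) {
  nt <- dim(dat)[1L]; nreg <- dim(dat)[2L]; n <- dim(dat)[3L]
  L <- nrow(tapers)
  k <- ncol(tapers)
  ## complex demodulation vectors, one per taper
  e <- exp(-2i * pi * f * (0:(L - 1)) / fs)
  te <- tapers * e                                 # L x k complex
  norm <- 2 / (fs * colSums(tapers^2))             # one-sided PSD scaling
  out <- matrix(NA_real_, nreg, length(centers))
  half <- (L - 1) / 2
  starts <- round((centers - t0) * fs) + 1 - floor(half)
  for (ci in seq_along(centers)) {
    s0 <- starts[ci]
    if (s0 < 1 || s0 + L - 1 > n) next
    idx <- s0:(s0 + L - 1)
    for (r in seq_len(nreg)) {
      ## trials x L slab; coefficient per trial and taper
      slab <- matrix(dat[, r, idx], nrow = nt)
      coefs <- slab %*% te                         # trials x k
      out[r, ci] <- mean(sweep(Mod(coefs)^2, 2, norm, "*"))
    }
  }
  out
}

#' Hanning-taper time-frequency representation (low frequencies)
#'
#' Adaptive window of four cycles per frequency multiplied by a Hanning
#' taper; power is the squared magnitude of the tapered Fourier coefficient,
#' averaged over trials, on a fixed time-bin grid. Bins whose window does not
#' fit inside the epoch are `NA` (missing, never zero).
#'
#' @param roi A [RoiSeries-class].
#' @param freqs Frequency grid in Hz (default 1--30 in 1-Hz steps).
#' @param tStep Time-bin step in seconds (default 0.005).
#' @param times Optional explicit bin centers (overrides `tStep`).
#' @return A [TimeFreqPower-class].
#' @export
tfrHanning <- function(roi, freqs = 1:30, tStep = 0.005, times = NULL) {
  stopifnot(is(roi, "RoiSeries"))
  if (length(freqs) == 0) stop("empty frequency list")
  fs <- roi@fs
  if (max(freqs) >= fs / 2) stop("fs too low for the requested frequencies")
  tAx <- timeAxis(roi)
  if (is.null(times))
    times <- seq(tAx[1L], tAx[length(tAx)], by = tStep)
  pow <- array(NA_real_, dim = c(dim(roi@data)[2L], length(freqs),
                                 length(times)))
  for (fi in seq_along(freqs)) {
    f <- freqs[fi]
    L <- max(4L, round(4 / f * fs))              # four cycles per frequency
    h <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / (L - 1))
    pow[, fi, ] <- .slidingPower(roi@data, fs, roi@t0, f, times,
                                 matrix(h, ncol = 1))
  }
  new("TimeFreqPower", power = pow, freqs = as.numeric(freqs), times = times,
      regionLabels = seriesLabels(roi),
      method = rep("hanning", length(freqs)))
}

#' Slepian multitaper time-frequency representation (high frequencies)
#'
#' Fixed sliding window (default 50 ms) tapered with `nTapers` discrete
#' prolate spheroidal sequences at time-bandwidth product NW = 2 (the only NW
#' for which three tapers are well concentrated; note the implied +-40 Hz
#' smoothing at a 50-ms window). Power is the mean over tapers of the
#' squared tapered Fourier coefficient, averaged over trials.
#'
#' @param roi A [RoiSeries-class].
#' @param freqs Frequency grid in Hz (default 30--100 in 2-Hz steps).
#' @param nTapers Number of Slepian tapers (default 3; must not exceed
#'   2 NW - 1).
#' @param windowS Window length in seconds (default 0.050).
#' @param nw Time-bandwidth product (default 2).
#' @param tStep Time-bin step in seconds (default 0.005).
#' @param times Optional explicit bin centers.
#' @return A [TimeFreqPower-class].
#' @export
tfrMultitaper <- function(roi, freqs = seq(30, 100, 2), nTapers = 3,
                          windowS = 0.050, nw = 2, tStep = 0.005,
                          times = NULL) {
  stopifnot(is(roi, "RoiSeries"))
  if (length(freqs) == 0) stop("empty frequency list")
  fs <- roi@fs
  if (max(freqs) >= fs / 2) stop("fs too low for the requested frequencies")
  L <- round(windowS * fs)
  if (L > dim(roi@data)[3L]) stop("window does not fit in the epoch")
  tapers <- dpssTapers(L, nw = nw, k = nTapers)
  tAx <- timeAxis(roi)
  if (is.null(times))
    times <- seq(tAx[1L], tAx[length(tAx)], by = tStep)
  pow <- array(NA_real_, dim = c(dim(roi@data)[2L], length(freqs),
                                 length(times)))
  for (fi in seq_along(freqs))
    pow[, fi, ] <- .slidingPower(roi@data, fs, roi@t0, freqs[fi], times,
                                 tapers)
  new("TimeFreqPower", power = pow, freqs = as.numeric(freqs), times = times,
      regionLabels = seriesLabels(roi),
      method = rep("multitaper", length(freqs)))
}

#' Normalize a mean power spectrum to unit total
#'
#' Divides by the sum of power estimates over the whole frequency range, so
#' regions and groups with different absolute power become comparable.
#'
#' @param meanPowerByFreq Non-negative power vector over the frequency grid.
#' @return Vector proportional to the input, summing to exactly 1.
#' @export
normalizeSpectrum <- function(meanPowerByFreq) {
  if (any(meanPowerByFreq < 0, na.rm = TRUE))
    stop("power must be non-negative")
  s <- sum(meanPowerByFreq, na.rm = TRUE)
  if (!is.finite(s) || s <= 0) stop("spectrum has no positive entries")
  meanPowerByFreq / s
}

#' Band-averaged power time course
#'
#' Mean over the in-band frequency rows of a [TimeFreqPower-class], per time
#' bin, restricted to a time window. Missing bins propagate as `NA`.
#'
#' @param tfr A [TimeFreqPower-class].
#' @param region Region label to extract.
#' @param band `c(fLo, fHi)` in Hz.
#' @param window `c(tLo, tHi)` in seconds.
#' @return Named numeric vector over the retained time bins.
#' @export
bandPowerTimecourse <- function(tfr, region, band, window) {
  stopifnot(is(tfr, "TimeFreqPower"))
  r <- match(region, tfr@regionLabels)
  if (is.na(r)) stop("unknown region: ", region)
  fIdx <- which(tfr@freqs >= band[1] & tfr@freqs <= band[2])
  tIdx <- which(tfr@times >= window[1] & tfr@times <= window[2])
  if (length(fIdx) == 0 || length(tIdx) == 0)
    stop("empty band/window intersection")
  m <- tfr@power[r, fIdx, tIdx, drop = FALSE]
  out <- apply(m, 3, mean)                       # NA propagates by default
  names(out) <- format(tfr@times[tIdx])
  out
}
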