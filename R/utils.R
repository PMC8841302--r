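#' @include AllClasses.R
NULL

## Evaluate expr with a private RNG stream, restoring the caller's state.
localSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

## Deterministic per-subject substream seed below 2^31.
substreamSeed <- function(master, index) {
  (as.double(master) * 1009 + 7919 * as.double(index)) %% 2147483629
}

## 1/f^exponent background noise, unit variance, zero mean. Spectrum shaping
## in the frequency domain with random phases.
pinkNoise <- function(n, exponent = 1, fs = 1) {
  stopifnot(n >= 4)
  nf <- floor(n / 2)
  f <- seq_len(nf) * fs / n
  amp <- f^(-exponent / 2)
  ph <- runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = ph)
  full <- complex(real = numeric(n))
  full[2:(nf + 1)] <- spec
  if (n %% 2 == 0) {
    full[nf + 1] <- complex(real = amp[nf] * cos(ph[nf]))  # Nyquist bin real
    if (nf > 1) full[n:(n - nf + 2)] <- Conj(spec[1:(nf - 1)])
  } else {
    full[n:(n - nf + 1)] <- Conj(spec)
  }
  x <- Re(fft(full, inverse = TRUE)) / n
  x <- x - mean(x)
  x / sd(x)
}

## Raised-cosine band mask over the positive-frequency axis.
## passband [f1, f2], cosine transitions of width tw on each side.
.bandMask <- function(freqs, f1, f2, tw) {
  m <- numeric(length(freqs))
  inb <- freqs >= f1 & freqs <= f2
  m[inb] <- 1
  lo <- freqs >= f1 - tw & freqs < f1
  m[lo] <- 0.5 * (1 + cos(pi * (f1 - freqs[lo]) / tw))
  hi <- freqs > f2 & freqs <= f2 + tw
  m[hi] <- 0.5 * (1 + cos(pi * (freqs[hi] - f2) / tw))
  m
}

## Forward FFT of a samples x trials matrix, reused across bands.
.epochSpectrum <- function(X) mvfft(X)

## Band-limited analytic signal from a precomputed spectrum F (samples x
## trials): positive frequencies are masked with a raised-cosine band and
## doubled, negative frequencies zeroed (one-step band-pass + Hilbert).
.bandAnalyticFromSpectrum <- function(F, fs, f1, f2, tw) {
  n <- nrow(F)
  k <- 0:(n - 1)
  freqs <- k * fs / n
  pos <- k > 0 & k < n / 2
  h <- numeric(n)
  h[pos] <- 2 * .bandMask(freqs[pos], f1, f2, tw)
  if (n %% 2 == 0) h[n / 2 + 1] <- .bandMask(fs / 2, f1, f2, tw)
  mvfft(F * h, inverse = TRUE) / n
}

## Band-limited analytic signal of each column of X (samples x trials).
bandAnalytic <- function(X, fs, f1, f2, tw = max(0.5, (f2 - f1) / 8)) {
  if (f1 <= 0) stop("band collapses: lower edge ", f1, " Hz <= 0")
  if (f2 >= fs / 2) stop("band upper edge ", f2, " Hz at or above Nyquist")
  .bandAnalyticFromSpectrum(.epochSpectrum(X), fs, f1, f2, tw)
}

## Plain analytic signal (full-band Hilbert) of each column of X.
analyticSignal <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[2:(n / 2)] <- 2
    h[n / 2 + 1] <- 1
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  mvfft(mvfft(X) * h, inverse = TRUE) / n
}

## Discrete prolate spheroidal (Slepian) tapers via the symmetric
## tridiagonal formulation; returns n x k matrix, unit-energy columns.
dpssTapers <- function(n, nw = 2, k = 3) {
  if (k > 2 * nw - 1 + 1e-9)
    stop("requested ", k, " tapers exceeds 2*NW - 1 = ", 2 * nw - 1)
  w <- nw / n
  i <- 0:(n - 1)
  A <- matrix(0, n, n)
  diag(A) <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  off <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A[cbind(1:(n - 1), 2:n)] <- off
  A[cbind(2:n, 1:(n - 1))] <- off
  e <- eigen(A, symmetric = TRUE)
  tap <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    tap[, j] <- tap[, j] / sqrt(sum(tap[, j]^2))
    # sign convention: symmetric tapers positive mean, antisymmetric positive
    # initial slope (sign is irrelevant for power but fixed for determinism)
    s <- sum(tap[, j])
    if (abs(s) > 1e-8) {
      if (s < 0) tap[, j] <- -tap[, j]
    } else if (tap[2, j] - tap[1, j] < 0) tap[, j] <- -tap[, j]
  }
  tap
}

## 4-connected (or 8-connected) component labeling of a logical matrix.
## Returns an integer matrix of component ids (0 = background).
connectedComponents <- function(mask, connectivity = 4) {
  stopifnot(connectivity %in% c(4, 8))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  if (connectivity == 4) {
    dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  } else {
    dr <- rep(c(-1L, 0L, 1L), 3L); dc <- rep(c(-1L, 0L, 1L), each = 3L)
    keep <- !(dr == 0L & dc == 0L); dr <- dr[keep]; dc <- dc[keep]
  }
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      r0 <- ((v - 1L) %% nr) + 1L
      c0 <- ((v - 1L) %/% nr) + 1L
      rr <- r0 + dr; cc <- c0 + dc
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      nb <- (cc[ok] - 1L) * nr + rr[ok]
      nb <- nb[mask[nb] & lab[nb] == 0L]
      if (length(nb)) {
        lab[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  lab
}
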