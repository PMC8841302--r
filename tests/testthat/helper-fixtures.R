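# Shared fixtures: everything generated in code at test time.

# Epoched sine: same waveform in every trial/channel unless noise > 0.
sineEpochs <- function(f, fs = 600, n = 1800, trials = 2, channels = 3,
                       phase = 0, noise = 0, seed = 1) {
  t <- (0:(n - 1)) / fs
  base <- sin(2 * pi * f * t + phase)
  d <- array(rep(base, each = trials * channels),
             c(trials, channels, n))
  if (noise > 0) {
    set.seed(seed)
    d <- d + array(rnorm(length(d), sd = noise), dim = dim(d))
  }
  epochedSeries(d, fs = fs)
}

# Small desk-scale simulation config reused across tests.
deskConfig <- function(...) {
  defaults <- list(nResponder = 2, nNonResponder = 2, nHc = 2, nTrials = 10,
                   fs = 300, epochLenS = 0.5, preStimS = 0.2)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulationConfig, args)
}

# One subject's comodulogram at reduced cost (single pathway window).
quickComod <- function(group, seed, kappa = NULL, trials = 40, fs = 300,
                       ampFreqs = seq(30, 80, 2)) {
  kb <- c(responder = 0.6, non_responder = 0.2, HC = 0.6)
  ks <- 0.1
  if (!is.null(kappa)) {
    kb[] <- kappa
    ks <- 0
  }
  cfg <- simulationConfig(nResponder = 1, nNonResponder = 1, nHc = 1,
                          nTrials = trials, fs = fs, epochLenS = 1.0,
                          preStimS = 0.2, kappaByGroup = kb, kappaSd = ks)
  s <- simulateSubject(cfg, group, seed = seed)
  comodulogram(s$roi, "rTHA", "rAMG", c(0, 0.05), ampFreqs = ampFreqs)
}

# Pooled region x time matrix of a RoiSeries (demeaned correlation checks).
pooledMatrix <- function(roi) {
  d <- seriesData(roi)
  t(matrix(aperm(d, c(2, 1, 3)), nrow = dim(d)[2L]))
}
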