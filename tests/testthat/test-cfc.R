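test_that("phase and envelope extraction recover analytic-signal ground truth", {
  fs <- 600; n <- 3000
  t <- (0:(n - 1)) / fs
  r <- roiSeries(array(cos(2 * pi * 40 * t), c(1, 1, n)), fs = fs,
                 regionLabels = "rAMG")
  env <- phaseEnvelope(r, "rAMG", 40, "envelope", halfWidth = 5)
  i <- 500:2500
  expect_lt(sd(env[1, i]) / mean(env[1, i]), 0.02)

  ph <- phaseEnvelope(r, "rAMG", 40, "phase", halfWidth = 5)
  d <- diff(ph[1, i])
  d <- d + (d < -pi) * 2 * pi - (d > pi) * 2 * pi
  expect_lt(abs(mean(d) * fs / (2 * pi) - 40) / 40, 0.01)

  # amplitude-modulated carrier: envelope tracks the modulator
  A <- 1 + 0.5 * cos(2 * pi * 10 * t)
  rm <- roiSeries(array(A * cos(2 * pi * 60 * t), c(1, 1, n)), fs = fs,
                  regionLabels = "rAMG")
  envm <- phaseEnvelope(rm, "rAMG", 60, "envelope")
  expect_gt(cor(envm[1, i], A[i]), 0.99)
})

test_that("band placement is validated", {
  r <- roiSeries(array(rnorm(300), c(1, 1, 300)), fs = 300,
                 regionLabels = "rAMG")
  expect_error(phaseEnvelope(r, "rAMG", 10, "envelope", halfWidth = 12),
               "collapses")
  expect_error(phaseEnvelope(r, "rAMG", 145, "envelope", halfWidth = 10),
               "Nyquist")
  expect_error(phaseEnvelope(r, "lOFC", 10, "phase"), "unknown region")
})

test_that("pac coherence matches its closed form for cosine modulation", {
  # env = 1 + cos(phi), phi covering whole cycles uniformly:
  # E[env e^{-i phi}] = 1/2, E[env^2] = 3/2, value = (1/2)/sqrt(3/2) = 1/sqrt(6)
  phi <- matrix(seq(0, 100 * 2 * pi, length.out = 12001)[-1], nrow = 1)
  env <- 1 + cos(phi)
  expect_equal(pacCoherence(phi, env), 1 / sqrt(6), tolerance = 1e-3)

  # constant envelope, uniform phase over whole cycles: phasor cancellation
  expect_lt(pacCoherence(phi, matrix(1, nrow = 1, ncol = ncol(phi))), 0.05)
})

test_that("independent phase and envelope stay below the shuffled null", {
  set.seed(41)
  hits <- 0
  for (i in 1:50) {
    phi <- matrix(runif(400, 0, 2 * pi), 4)
    env <- matrix(abs(rnorm(400)) + 0.5, 4)
    obs <- pacCoherence(phi, env)
    null <- vapply(1:99, function(j)
      pacCoherence(phi, env[sample(4), sample(100)]), numeric(1))
    hits <- hits + (obs < quantile(null, 0.95))
  }
  expect_gte(hits, 45)                          # >= 90% of simulations
})

test_that("pac coherence is bounded and invariant to rotation and scale", {
  set.seed(42)
  phi <- matrix(runif(600, 0, 2 * pi), 3)
  env <- matrix(rexp(600), 3)
  v <- pacCoherence(phi, env)
  expect_gte(v, 0); expect_lte(v, 1)
  expect_equal(pacCoherence(phi + 1.234, env), v, tolerance = 1e-12)
  expect_equal(pacCoherence(phi, 5.67 * env), v, tolerance = 1e-12)
  expect_equal(pacCoherence(phi, env * 0), 0)
  expect_error(pacCoherence(phi, env[, 1:100]), "mismatch")
})

test_that("mvl estimator variant is exposed and bounded", {
  phi <- matrix(seq(0, 60 * 2 * pi, length.out = 6001)[-1], nrow = 1)
  env <- 1 + 0.8 * cos(phi)
  v <- pacCoherence(phi, env, estimator = "mvl")
  expect_equal(v, 0.4, tolerance = 1e-3)         # (kappa/2) / 1
  expect_lte(v, 1)
})

test_that("injected coupling is recovered at the injected grid location", {
  cm <- quickComod("responder", seed = 301, kappa = 0.8,
                   ampFreqs = 30:100)
  v <- couplingValues(cm)
  am <- which(v == max(v), arr.ind = TRUE)
  expect_lte(abs(phaseFreqs(cm)[am[1]] - 10), 1)
  expect_lte(abs(ampFreqs(cm)[am[2]] - 60), ampHalfWidth(8:13))
})

test_that("comodulogram mean increases with modulation depth", {
  reps <- 3
  meanPac <- vapply(c(0.2, 0.4, 0.6, 0.8), function(k) {
    mean(vapply(seq_len(reps), function(r) {
      mean(couplingValues(quickComod("responder", seed = 500 + 17 * r,
                                     kappa = k, trials = 20)))
    }, numeric(1)))
  }, numeric(1))
  expect_identical(order(meanPac), 1:4)
})

test_that("kappa = 0 comodulograms stay at the trial-shuffled chance level", {
  # per-bin 99th-percentile null from shuffling the trial pairing between
  # the phase region and the envelope region within each subject
  set.seed(43)
  exceed <- 0
  n <- 12
  grid <- seq(30, 80, 10)
  for (i in seq_len(n)) {
    cfg <- simulationConfig(nResponder = 1, nNonResponder = 1, nHc = 1,
                            nTrials = 15, fs = 300, epochLenS = 0.6,
                            preStimS = 0.2,
                            kappaByGroup = c(responder = 0, non_responder = 0,
                                             HC = 0), kappaSd = 0)
    s <- simulateSubject(cfg, "HC", seed = 700 + i)
    v <- couplingValues(comodulogram(s$roi, "rTHA", "rAMG", c(0, 0.05),
                                     ampFreqs = grid))
    d <- seriesData(s$roi)
    amp <- match("rAMG", seriesLabels(s$roi))
    nullMats <- lapply(1:100, function(j) {
      ds <- d
      ds[, amp, ] <- d[sample(nrow(d)), amp, ]   # break the trial pairing
      couplingValues(comodulogram(
        roiSeries(ds, fs = samplingRate(s$roi), t0 = timeOnset(s$roi),
                  regionLabels = seriesLabels(s$roi)),
        "rTHA", "rAMG", c(0, 0.05), ampFreqs = grid))
    })
    thr <- apply(simplify2array(nullMats), c(1, 2), quantile, probs = 0.99)
    exceed <- exceed + any(v > thr)
  }
  expect_lte(exceed / n, 0.35)
})

test_that("the region-pair statistic is asymmetric by construction", {
  cfg <- deskConfig(nTrials = 15, epochLenS = 0.6)
  s <- simulateSubject(cfg, "responder", seed = 44)
  a <- couplingValues(comodulogram(s$roi, "rTHA", "rAMG", c(0, 0.05),
                                   ampFreqs = seq(30, 80, 10)))
  b <- couplingValues(comodulogram(s$roi, "rAMG", "rTHA", c(0, 0.05),
                                   ampFreqs = seq(30, 80, 10)))
  expect_gt(max(abs(a - b)), 1e-6)
})

test_that("degenerate comodulogram windows are rejected", {
  cfg <- deskConfig(nTrials = 3, epochLenS = 0.5)
  s <- simulateSubject(cfg, "HC", seed = 45)
  expect_error(comodulogram(s$roi, "rTHA", "rAMG", c(0, 0.001)),
               "shorter than 2")
  expect_error(comodulogram(s$roi, "rTHA", "rAMG", c(0, 0.05),
                            phaseFreqs = numeric(0)), "empty")
})
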