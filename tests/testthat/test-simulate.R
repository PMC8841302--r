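test_that("identical config and seed reproduce tensors exactly", {
  cfg <- deskConfig()
  a <- simulateSubject(cfg, "responder", seed = 7)
  b <- simulateSubject(cfg, "responder", seed = 7)
  expect_identical(seriesData(a$roi), seriesData(b$roi))
  expect_identical(a$subject, b$subject)
  expect_false(identical(
    seriesData(simulateSubject(cfg, "responder", seed = 8)$roi),
    seriesData(a$roi)))
})

test_that("cohort has the configured group sizes and consistent labels", {
  co <- simulateCohort(deskConfig(nResponder = 5, nNonResponder = 6, nHc = 4))
  expect_equal(as.integer(table(co$subjects$group)[c("non_responder",
                                                     "responder", "HC")]),
               c(6L, 5L, 4L))
  pat <- co$subjects[co$subjects$group != "HC", ]
  expect_equal(classifyResponse(pat$reductionRatio), pat$group)
  expect_equal(pat$reductionRatio,
               reductionRatio(pat$hamd6Baseline, pat$hamd6Endpoint))
  expect_true(all(is.na(co$subjects$reductionRatio[
    co$subjects$group == "HC"])))
})

test_that("default cohort sizes match the analyzed study sample", {
  cfg <- simulationConfig()
  expect_equal(cfg$nNonResponder, 33L)
  expect_equal(cfg$nResponder, 32L)
  expect_equal(cfg$nHc, 29L)
})

test_that("single-trial simulation remains valid downstream", {
  co <- simulateCohort(deskConfig(nResponder = 1, nNonResponder = 1,
                                  nHc = 1, nTrials = 1))
  expect_equal(nTrials(co$roi[[1]]), 1L)
  cm <- comodulogram(co$roi[[1]], "rTHA", "rAMG", c(0, 0.05),
                     ampFreqs = seq(30, 80, 10))
  expect_true(all(couplingValues(cm) >= 0 & couplingValues(cm) <= 1))
})

test_that("background spectrum follows the configured 1/f slope", {
  cfg <- deskConfig(nTrials = 30, epochLenS = 2, noiseExponent = 1)
  s <- simulateSubject(cfg, "HC", seed = 3)
  x <- seriesData(s$roi)[, match("lAMG", seriesLabels(s$roi)), ]
  ps <- apply(x, 1, function(v) Mod(fft(v))^2)
  n <- ncol(x)
  fr <- (0:(n - 1)) * samplingRate(s$roi) / n
  keep <- fr > 2 & fr < 100
  slope <- coef(lm(log(rowMeans(ps)[keep]) ~ log(fr[keep])))[2]
  expect_lt(abs(slope - (-1)), 0.3)
})

test_that("gamma envelope tracks driver phase more strongly as kappa rises", {
  # circular-linear association inside the coupling window, averaged over
  # replicates, must be strictly monotone in kappa
  kappas <- c(0, 0.3, 0.6, 0.9)
  reps <- 5
  assoc <- vapply(kappas, function(k) {
    mean(vapply(seq_len(reps), function(r) {
      cfg <- deskConfig(nTrials = 20, kappaByGroup = c(responder = k,
                                                       non_responder = k,
                                                       HC = k), kappaSd = 0)
      s <- simulateSubject(cfg, "HC", seed = 100 * r + 7)
      env <- phaseEnvelope(s$roi, "rAMG", 60, "envelope")
      ph <- phaseEnvelope(s$roi, "rTHA", 10, "phase")
      w <- which(timeAxis(s$roi) >= 0 & timeAxis(s$roi) <= 0.05)
      # circular-linear correlation: R of env ~ cos(phase) + sin(phase)
      e <- as.vector(env[, w]); p <- as.vector(ph[, w])
      sqrt(summary(lm(e ~ cos(p) + sin(p)))$r.squared)
    }, numeric(1)))
  }, numeric(1))
  expect_identical(order(assoc), seq_along(kappas))
  expect_gt(assoc[4], assoc[1] + 0.1)
})

test_that("non-responder driver alpha is attenuated in the stated windows", {
  cfg <- deskConfig(nTrials = 1, alphaAmp = 50)   # oscillation dominates
  nr <- simulateSubject(cfg, "non_responder", seed = 5)
  re <- simulateSubject(cfg, "responder", seed = 5)
  t <- timeAxis(nr$roi)
  inw <- t >= 0.022 & t <= 0.048
  outw <- t >= 0.06 & t <= 0.12
  r <- match("rTHA", seriesLabels(nr$roi))
  ratioIn <- sd(seriesData(nr$roi)[1, r, inw]) /
    sd(seriesData(re$roi)[1, r, inw])
  ratioOut <- sd(seriesData(nr$roi)[1, r, outw]) /
    sd(seriesData(re$roi)[1, r, outw])
  expect_lt(ratioIn, 0.7)
  expect_gt(ratioOut, 0.9)
})

test_that("config validation rejects inconsistent settings", {
  expect_error(deskConfig(kappaByGroup = c(responder = 1.2,
                                           non_responder = 0.2, HC = 0.6)),
               "kappa")
  expect_error(deskConfig(couplingWindows = data.frame(
    phaseRegion = "rTHA", ampRegion = "rAMG", tStart = 0, tEnd = 0.9)),
    "within")
  expect_error(deskConfig(fs = 100), "fs too low")
  expect_error(simulateSubject(deskConfig(), "patient"), "unknown group")
})

test_that("sensor projection respects the lead field and requested SNR", {
  cfg <- deskConfig(nTrials = 4)
  s <- simulateSubject(cfg, "HC", seed = 2)
  # identity-like gain: one sensor per source
  lfI <- new("ToyLeadField", gain = diag(6), roiMap = DUAL_PATHWAY_ROIS)
  sens <- projectToSensors(s$roi, lfI, snrDb = Inf)
  expect_equal(seriesData(sens), seriesData(s$roi), ignore_attr = TRUE)

  # noiseless output lies in the gain column space
  lf <- toyLeadField(nSensors = 12, seed = 4)
  sens2 <- projectToSensors(s$roi, lf, snrDb = Inf)
  proj <- lf@gain %*% solve(crossprod(lf@gain), t(lf@gain))
  x <- matrix(seriesData(sens2)[1, , ], nrow = 12)
  expect_lt(max(abs(x - proj %*% x)), 1e-10)

  # snr 0 dB: signal and noise power match within 10%
  cfgL <- deskConfig(nTrials = 20, epochLenS = 2)
  sl <- simulateSubject(cfgL, "HC", seed = 6)
  clean <- projectToSensors(sl$roi, lf, snrDb = Inf)
  noisy <- projectToSensors(sl$roi, lf, snrDb = 0, seed = 9)
  sigPow <- mean(seriesData(clean)^2)
  noisePow <- mean((seriesData(noisy) - seriesData(clean))^2)
  expect_lt(abs(noisePow / sigPow - 1), 0.1)
})
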