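#' @include AllClasses.R utils.R
NULL

#' Simulation configuration for synthetic dual-pathway cohorts
#'
#' Describes a cohort of epoched six-ROI source-level recordings of a sad-face
#' viewing task: 1/f background activity everywhere, alpha-band drivers in the
#' right thalamus and right orbitofrontal cortex, and gamma activity in the
#' right amygdala whose envelope is modulated by the driver's alpha phase
#' inside two pathway-specific windows (thalamic 0--50 ms, orbitofrontal
#' 100--200 ms after stimulus onset). Patients' HAM-D-6 reduction ratios are
#' drawn from a linear-Gaussian clinical model of the subject's realized
#' coupling depth, so coupling strength and symptom improvement are
#' statistically linked by construction.
#'
#' @param nResponder,nNonResponder,nHc Group sizes (default 32/33/29).
#' @param nTrials Trials per subject (default 40).
#' @param epochLenS Post-stimulus epoch length in seconds (default 3).
#' @param preStimS Pre-stimulus padding in seconds (default 0.5); low-frequency
#'   time-frequency windows near stimulus onset extend into it.
#' @param fs Sampling rate in Hz (default 600; 1200 matches the recording
#'   hardware but doubles cost with no analytic benefit below 100 Hz).
#' @param roiLabels The six dual-pathway region labels.
#' @param alphaFreq Driver frequency in Hz, within 8--13 (default 10).
#' @param gammaFreq Amygdala carrier frequency in Hz, within 30--80
#'   (default 60).
#' @param couplingWindows Data frame with columns `phaseRegion`, `ampRegion`,
#'   `tStart`, `tEnd` (seconds after onset); defaults to the two pathway
#'   windows (rTHA->rAMG 0--0.05 s, rOFC->rAMG 0.1--0.2 s).
#' @param kappaByGroup Named modulation depths in [0, 1]; defaults
#'   responder = 0.6, non_responder = 0.2, HC = 0.6.
#' @param kappaSd Subject-level SD of the realized modulation depth around its
#'   group value (truncated to [0, 1]; default 0.1).
#' @param alphaPowerAttenuation Multiplier (< 1) applied to the rTHA alpha
#'   driver over 20--50 ms and the rOFC driver over 110--145 ms for
#'   non-responders (default 0.5).
#' @param alphaAmp,gammaAmp Oscillation amplitudes relative to the
#'   unit-variance 1/f background (both default 1; emotional-face tasks show
#'   strong gamma and comparatively weak alpha activation in these regions).
#' @param noiseExponent 1/f spectral slope of the background (default 1).
#' @param snrDb Sensor-level SNR in dB used by [projectToSensors()]
#'   (default 10; `Inf` = noiseless).
#' @param clinicalIntercept,clinicalSlope,clinicalSd Linear-Gaussian map from
#'   realized kappa to the HAM-D-6 reduction ratio (defaults 0.2, 0.75, 0.1:
#'   group means 0.35 and 0.65 straddle the 50% responder threshold).
#' @param couplingPhase Preferred coupling phase phi0 in radians (default 0).
#' @param seed Master RNG seed (default 1).
#'
#' @return A validated list of class `SimulationConfig`.
#' @examples
#' cfg <- simulationConfig(nResponder = 2, nNonResponder = 2, nHc = 1,
#'                         nTrials = 4, fs = 300, epochLenS = 0.5,
#'                         preStimS = 0.1)
#' cohort <- simulateCohort(cfg)
#' table(cohort$subjects$group)
#' @export
simulationConfig <- function(nResponder = 32L, nNonResponder = 33L,
                             nHc = 29L, nTrials = 40L, epochLenS = 3.0,
                             preStimS = 0.5, fs = 600,
                             roiLabels = DUAL_PATHWAY_ROIS,
                             alphaFreq = 10, gammaFreq = 60,
                             couplingWindows = NULL,
                             kappaByGroup = c(responder = 0.6,
                                              non_responder = 0.2, HC = 0.6),
                             kappaSd = 0.1, alphaPowerAttenuation = 0.5,
                             alphaAmp = 1, gammaAmp = 1,
                             noiseExponent = 1, snrDb = 10,
                             clinicalIntercept = 0.2, clinicalSlope = 0.75,
                             clinicalSd = 0.1, couplingPhase = 0, seed = 1L) {
  if (is.null(couplingWindows))
    couplingWindows <- data.frame(
      phaseRegion = c("rTHA", "rOFC"), ampRegion = c("rAMG", "rAMG"),
      tStart = c(0.0, 0.1), tEnd = c(0.05, 0.2),
      stringsAsFactors = FALSE)
  cfg <- list(nResponder = as.integer(nResponder),
              nNonResponder = as.integer(nNonResponder), nHc = as.integer(nHc),
              nTrials = as.integer(nTrials), epochLenS = epochLenS,
              preStimS = preStimS, fs = fs, roiLabels = roiLabels,
              alphaFreq = alphaFreq, gammaFreq = gammaFreq,
              couplingWindows = couplingWindows, kappaByGroup = kappaByGroup,
              kappaSd = kappaSd,
              alphaPowerAttenuation = alphaPowerAttenuation,
              alphaAmp = alphaAmp, gammaAmp = gammaAmp,
              noiseExponent = noiseExponent, snrDb = snrDb,
              clinicalIntercept = clinicalIntercept,
              clinicalSlope = clinicalSlope, clinicalSd = clinicalSd,
              couplingPhase = couplingPhase, seed = as.integer(seed))
  class(cfg) <- "SimulationConfig"
  validateSimulationConfig(cfg)
  cfg
}

validateSimulationConfig <- function(cfg) {
  with(cfg, {
    if (any(c(nResponder, nNonResponder, nHc, nTrials) <= 0))
      stop("all counts must be positive")
    if (any(kappaByGroup < 0 | kappaByGroup > 1))
      stop("kappa outside [0, 1]")
    if (!all(c("responder", "non_responder", "HC") %in% names(kappaByGroup)))
      stop("kappaByGroup must name responder, non_responder and HC")
    if (alphaFreq < 8 || alphaFreq > 13)
      stop("alphaFreq must lie in [8, 13] Hz")
    if (gammaFreq < 30 || gammaFreq > 80)
      stop("gammaFreq must lie in [30, 80] Hz")
    if (any(couplingWindows$tStart < 0) ||
        any(couplingWindows$tEnd > epochLenS) ||
        any(couplingWindows$tEnd <= couplingWindows$tStart))
      stop("coupling windows must lie within [0, epochLenS]")
    ## Nyquist margin: gamma envelope bands extend ~16 Hz above the carrier
    if (fs <= 2 * (gammaFreq + 20))
      stop("fs too low for the gamma band plus smoothing bandwidth")
    if (alphaPowerAttenuation >= 1 || alphaPowerAttenuation <= 0)
      stop("alphaPowerAttenuation must lie in (0, 1)")
  })
  invisible(cfg)
}

## Windows of attenuated driver alpha for non-responders (seconds after
## onset), matching the pathway-specific alpha power deficits being emulated.
.ALPHA_ATTEN_WINDOWS <- list(rTHA = c(0.020, 0.050), rOFC = c(0.110, 0.145))

#' Simulate one subject's source-level recording and clinical record
#'
#' Each ROI is unit-variance 1/f noise; the right thalamus and right OFC
#' additionally carry an alpha oscillation with trial-random phase; the right
#' amygdala carries a gamma oscillation whose envelope, inside each coupling
#' window, is `gammaAmp * (1 + kappa * cos(phase_driver - phi0))` and
#' `gammaAmp` elsewhere. Non-responders have their driver alpha scaled by
#' `alphaPowerAttenuation` inside 20--50 ms (rTHA) and 110--145 ms (rOFC).
#' Patients receive HAM-D-6 scores whose reduction ratio follows the linear
#' clinical model of the realized kappa; the recorded group label always
#' equals the >= 50% rule applied to the integer-score-derived ratio.
#'
#' @param config A [simulationConfig()].
#' @param group One of `"responder"`, `"non_responder"`, `"HC"`.
#' @param seed Seed for this subject's private RNG stream.
#' @param id Subject identifier stored in the record.
#' @return List with elements `roi` ([RoiSeries-class]) and `subject`
#'   (one-row data frame: id, group, hamd17Baseline, hamd6Baseline,
#'   hamd6Endpoint, reductionRatio, age, sex, education, trueKappa).
#' @export
simulateSubject <- function(config, group, seed = config$seed,
                            id = paste0(group, "_1")) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (!group %in% names(config$kappaByGroup))
    stop("unknown group: ", group)
  localSeed(seed, {
    fs <- config$fs
    n <- round((config$preStimS + config$epochLenS) * fs)
    t <- (seq_len(n) - 1) / fs - config$preStimS
    nt <- config$nTrials
    rois <- config$roiLabels
    kappa <- min(1, max(0, config$kappaByGroup[[group]] +
                             config$kappaSd * rnorm(1)))
    dat <- array(0, dim = c(nt, length(rois), n))

    for (r in seq_along(rois))
      for (tr in seq_len(nt))
        dat[tr, r, ] <- pinkNoise(n, config$noiseExponent, fs)

    drivers <- intersect(c("rTHA", "rOFC"), rois)
    phase0 <- list()  # per-driver per-trial ground-truth alpha phase offsets
    for (d in drivers) phase0[[d]] <- runif(nt, 0, 2 * pi)

    atten <- group == "non_responder"
    for (d in drivers) {
      r <- match(d, rois)
      aw <- .ALPHA_ATTEN_WINDOWS[[d]]
      scale <- rep(1, n)
      if (atten) scale[t >= aw[1] & t <= aw[2]] <- config$alphaPowerAttenuation
      for (tr in seq_len(nt))
        dat[tr, r, ] <- dat[tr, r, ] + config$alphaAmp * scale *
          cos(2 * pi * config$alphaFreq * t + phase0[[d]][tr])
    }

    if ("rAMG" %in% rois) {
      r <- match("rAMG", rois)
      cw <- config$couplingWindows
      for (tr in seq_len(nt)) {
        A <- rep(config$gammaAmp, n)
        for (w in seq_len(nrow(cw))) {
          d <- cw$phaseRegion[w]
          if (!d %in% drivers) next
          inw <- t >= cw$tStart[w] & t <= cw$tEnd[w]
          phi <- 2 * pi * config$alphaFreq * t[inw] + phase0[[d]][tr]
          A[inw] <- config$gammaAmp *
            (1 + kappa * cos(phi - config$couplingPhase))
        }
        psi <- runif(1, 0, 2 * pi)
        dat[tr, r, ] <- dat[tr, r, ] +
          A * cos(2 * pi * config$gammaFreq * t + psi)
      }
    }

    subject <- .clinicalRecord(config, group, id, kappa)
    list(roi = roiSeries(dat, fs = fs, t0 = -config$preStimS,
                         regionLabels = rois),
         subject = subject)
  })
}

## Draw demographics and HAM-D scores. The reduction ratio comes from the
## linear clinical model truncated to the intended group's side of the 50%
## threshold, so cohort group counts are exact and label-ratio consistency
## holds for any kappa.
.clinicalRecord <- function(config, group, id, kappa) {
  age <- round(min(60, max(18, rnorm(1, 31.5, 9))))
  sex <- sample(c("female", "male"), 1)
  education <- round(min(22, max(6, rnorm(1, 13.5, 2.8))))
  if (group == "HC")
    return(data.frame(id = id, group = group, hamd17Baseline = NA_real_,
                      hamd6Baseline = NA_real_, hamd6Endpoint = NA_real_,
                      reductionRatio = NA_real_, age = age, sex = sex,
                      education = education, trueKappa = kappa,
                      stringsAsFactors = FALSE))
  hamd17 <- round(max(18, rnorm(1, 23.5, 5)))
  baseline <- round(min(22, max(7, rnorm(1, 12, 2.5))))
  mu <- config$clinicalIntercept + config$clinicalSlope * kappa
  sdv <- config$clinicalSd
  ## draw the ratio from the clinical model truncated to the side of the
  ## responder threshold the group label demands (labels stay consistent
  ## with the >=50% rule for any kappa)
  bounds <- if (group == "responder") c(0.5, 1) else c(-0.5, 0.5 - 1e-9)
  lo <- pnorm((bounds[1] - mu) / sdv)
  hi <- pnorm((bounds[2] - mu) / sdv)
  if (hi - lo < 1e-12) {                      # far tail: pin to the boundary
    ratio <- if (group == "responder") bounds[1] else bounds[2]
  } else {
    ratio <- mu + sdv * qnorm(runif(1, lo, hi))
  }
  endpoint <- min(baseline, max(0, round(baseline * (1 - ratio))))
  ## integer rounding of the scores can flip the label across the boundary;
  ## nudge the endpoint to the nearest consistent score
  if (classifyResponse((baseline - endpoint) / baseline) != group)
    endpoint <- if (group == "responder") floor(baseline / 2)
                else floor(baseline / 2) + 1L
  finalRatio <- (baseline - endpoint) / baseline
  data.frame(id = id, group = group, hamd17Baseline = hamd17,
             hamd6Baseline = baseline, hamd6Endpoint = endpoint,
             reductionRatio = finalRatio, age = age, sex = sex,
             education = education, trueKappa = kappa,
             stringsAsFactors = FALSE)
}

#' Simulate a full cohort
#'
#' One subject per entry of the three groups, each on a deterministic RNG
#' substream derived from the master seed and the subject index, so results
#' are reproducible and unaffected by changes to other group sizes.
#'
#' @param config A [simulationConfig()].
#' @return List with `roi` (list of [RoiSeries-class], one per subject) and
#'   `subjects` (data frame, one row per subject).
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  groups <- c(rep("non_responder", config$nNonResponder),
              rep("responder", config$nResponder),
              rep("HC", config$nHc))
  roi <- vector("list", length(groups))
  recs <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    s <- simulateSubject(config, groups[i],
                         seed = substreamSeed(config$seed, i),
                         id = sprintf("S%03d", i))
    roi[[i]] <- s$roi
    recs[[i]] <- s$subject
  }
  list(roi = roi, subjects = do.call(rbind, recs))
}

#' Random toy lead field
#'
#' Gaussian gain columns (unit norm) with `sourcesPerRoi` sources assigned to
#' each ROI; full column rank almost surely, re-drawn if degenerate.
#'
#' @param nSensors Number of sensors.
#' @param roiLabels ROI labels owning the sources.
#' @param sourcesPerRoi Sources per ROI.
#' @param seed RNG seed.
#' @return A [ToyLeadField-class].
#' @export
toyLeadField <- function(nSensors = 30, roiLabels = DUAL_PATHWAY_ROIS,
                         sourcesPerRoi = 1, seed = 1) {
  localSeed(seed, {
    ns <- length(roiLabels) * sourcesPerRoi
    stopifnot(nSensors >= ns)
    repeat {
      gain <- matrix(rnorm(nSensors * ns), nSensors, ns)
      gain <- sweep(gain, 2, sqrt(colSums(gain^2)), "/")
      if (qr(gain)$rank == ns) break
    }
    new("ToyLeadField", gain = gain,
        roiMap = rep(roiLabels, each = sourcesPerRoi))
  })
}

#' Project ROI series through a lead field to sensors
#'
#' Each source carries the series of the ROI owning it; sensors are
#' `gain %*% sources` plus white noise scaled so that the pooled sensor
#' signal-to-noise power ratio equals `10^(snrDb/10)` (`Inf` = noiseless).
#'
#' @param roi A [RoiSeries-class].
#' @param lf A [ToyLeadField-class]; its `roiMap` must cover the ROI labels.
#' @param snrDb Signal-to-noise ratio in dB.
#' @param seed Optional seed for the sensor noise.
#' @return An [EpochedSeries-class] with one channel per sensor.
#' @export
projectToSensors <- function(roi, lf, snrDb = Inf, seed = NULL) {
  stopifnot(is(roi, "RoiSeries"), is(lf, "ToyLeadField"))
  labs <- seriesLabels(roi)
  if (!all(lf@roiMap %in% labs))
    stop("lead field references regions absent from the ROI series")
  src2roi <- match(lf@roiMap, labs)
  d <- dim(roi@data)
  nSens <- nrow(lf@gain)
  localSeed(seed, {
    out <- array(0, dim = c(d[1L], nSens, d[3L]))
    for (tr in seq_len(d[1L])) {
      srcs <- matrix(roi@data[tr, src2roi, ], nrow = length(src2roi))
      out[tr, , ] <- lf@gain %*% srcs
    }
    if (is.finite(snrDb)) {
      sigPow <- mean(out^2)
      noiseSd <- sqrt(sigPow / 10^(snrDb / 10))
      out <- out + array(rnorm(length(out), sd = noiseSd), dim = dim(out))
    }
    epochedSeries(out, fs = roi@fs, t0 = roi@t0,
                  channelLabels = paste0("sens", seq_len(nSens)))
  })
}
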