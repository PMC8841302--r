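#' @include AllClasses.R simulate.R preprocess.R source_recon.R spectral.R
#' @include cfc.R group_stats.R response_prediction.R
NULL

.pipelineDefaults <- function() {
  list(
    seed = 1L,
    outDir = NULL,
    verbose = FALSE,
    simulate = list(),                    # simulationConfig() overrides
    preprocess = list(enabled = TRUE, notch = 50, band = c(1, 100),
                      zThresh = 3, hook = NULL),
    source = list(enabled = FALSE, nSensors = 30, reg = 0.05,
                  aggregate = "sign-mean", orthogonalize = TRUE),
    tfr = list(enabled = FALSE, regions = c("rTHA", "rOFC", "rAMG"),
               alphaBand = c(8, 13), gammaBand = c(30, 80),
               window = c(0, 0.2), tStep = 0.005, q = 0.05),
    cfc = list(phaseFreqs = 8:13, ampFreqs = 30:100, estimator = "coherence"),
    stats = list(P = 1000, clusterAlpha = 0.05, connectivity = 4,
                 ampBand = c(30, 80)),
    predict = list(responderThreshold = 0.5)
  )
}

## Recursive merge with strict schema: unknown keys are an error.
.mergeConfig <- function(defaults, user, path = "") {
  for (k in names(user)) {
    if (!k %in% names(defaults))
      stop("unknown config key: ", paste0(path, k))
    if (is.list(defaults[[k]]) && !is.data.frame(defaults[[k]]) &&
        k != "simulate") {
      if (!is.list(user[[k]]))
        stop("config key ", paste0(path, k), " must be a list")
      defaults[[k]] <- .mergeConfig(defaults[[k]], user[[k]],
                                    paste0(path, k, "$"))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Pipeline run configuration
#'
#' Nested parameter blocks mirroring each stage's defaults, all of which
#' equal the analysis defaults (50-Hz notch, 1--100 Hz band, 8--13 Hz phase
#' and 30--100 Hz amplitude grids, 0--50 and 100--200 ms pathway windows,
#' 1000 permutations, 50% responder threshold). Unknown keys raise an error
#' naming the key. The `simulate` block takes [simulationConfig()] arguments.
#'
#' @param ... Named overrides of the defaults (nested lists for stage
#'   blocks), e.g. `stats = list(P = 200)`.
#' @return A `PipelineConfig` list.
#' @export
pipelineConfig <- function(...) {
  user <- list(...)
  if (length(user) == 1 && is.null(names(user)) && is.list(user[[1]]))
    user <- user[[1]]
  cfg <- .mergeConfig(.pipelineDefaults(), user)
  badSim <- setdiff(names(cfg$simulate),
                    names(formals(simulationConfig)))
  if (length(badSim))
    stop("unknown config key: simulate$", badSim[1])
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Load a pipeline configuration from a YAML file
#'
#' Reads a structured config file whose keys mirror [pipelineConfig()];
#' every field has a default and unknown keys are an error.
#'
#' @param path Path to a YAML file.
#' @return A `PipelineConfig` list.
#' @export
pipelineConfigFromYaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configs")
  pipelineConfig(yaml::read_yaml(path))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes simulate -> preprocess -> (optional sensor projection, LCMV and
#' orthogonalization round-trip) -> (optional band-power time courses with
#' pointwise F/FDR and post-hoc t) -> pathway comodulograms -> cluster
#' permutation tests (non-responder vs responder, both pathway windows) ->
#' per-subject cluster strengths -> correlation with reduction ratios ->
#' combined-feature ROC. All randomness derives from the single master seed;
#' reruns with an identical config are numerically identical.
#'
#' If no significant (p < 0.05) negative cluster exists in a window, the
#' largest-mass negative cluster is used for feature extraction (flagged in
#' the report); if there is none at all, the window contributes no feature.
#'
#' @param config A [pipelineConfig()].
#' @return A `PipelineRun` list: `config`, `subjects` (with appended feature
#'   columns), `powerStats` (when the tfr stage is enabled), `clusterTests`,
#'   `features`, `correlations`, `roc`, `demographics`, `stages` (log of
#'   executed stages with parameters).
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "PipelineConfig"))
  log <- list()
  say <- function(...) if (isTRUE(config$verbose)) message(sprintf(...))

  simArgs <- config$simulate
  simArgs$seed <- simArgs$seed %||% config$seed
  simCfg <- do.call(simulationConfig, simArgs)
  say("simulating cohort (%d subjects)",
      simCfg$nResponder + simCfg$nNonResponder + simCfg$nHc)
  cohort <- simulateCohort(simCfg)
  log$simulate <- simArgs

  if (isTRUE(config$preprocess$enabled)) {
    say("preprocessing")
    cohort$roi <- lapply(cohort$roi, function(r) {
      filt <- notchBandpass(r, notchHz = config$preprocess$notch,
                            band = config$preprocess$band,
                            shortEpoch = "warn")
      # artifact-cleaning hook: ICA-style manual cleaning is out of scope,
      # but user-supplied cleaners slot in here
      if (is.function(config$preprocess$hook))
        filt <- config$preprocess$hook(filt)
      rejectHighVariance(filt, zThresh = config$preprocess$zThresh)$data
    })
    log$preprocess <- config$preprocess
  }

  if (isTRUE(config$source$enabled)) {
    say("sensor projection and source reconstruction")
    lf <- toyLeadField(nSensors = config$source$nSensors,
                       roiLabels = simCfg$roiLabels,
                       seed = substreamSeed(config$seed, 90001))
    cohort$roi <- lapply(seq_along(cohort$roi), function(i) {
      sens <- projectToSensors(cohort$roi[[i]], lf, snrDb = simCfg$snrDb,
                               seed = substreamSeed(config$seed, 91000 + i))
      filt <- lcmvFilters(lf, sensorCovariance(sens),
                          reg = config$source$reg)
      rec <- applyFilters(sens, filt, lf,
                          aggregate = config$source$aggregate)
      if (isTRUE(config$source$orthogonalize))
        rec <- symmetricOrthogonalize(rec)
      rec
    })
    log$source <- config$source
  }

  powerStats <- NULL
  if (isTRUE(config$tfr$enabled)) {
    say("band-power time courses and pointwise F/FDR")
    tc <- config$tfr
    powerStats <- list()
    for (reg in tc$regions) {
      for (bandName in c("alpha", "gamma")) {
        band <- if (bandName == "alpha") tc$alphaBand else tc$gammaBand
        rows <- do.call(rbind, lapply(cohort$roi, function(r) {
          tfr <- if (bandName == "alpha")
            tfrHanning(r, freqs = seq(band[1], band[2]), tStep = tc$tStep)
          else
            tfrMultitaper(r, freqs = seq(band[1], band[2], 2),
                          tStep = tc$tStep)
          bandPowerTimecourse(tfr, reg, band, tc$window)
        }))
        grp <- split(seq_len(nrow(rows)), cohort$subjects$group)
        valid <- colSums(is.na(rows)) == 0
        groups <- lapply(grp[c("non_responder", "responder", "HC")],
                         function(i) rows[i, valid, drop = FALSE])
        f <- pointwiseFFdr(groups, q = tc$q)
        post <- if (any(f$mask))
          posthocT(groups[[1]], groups[[2]], f$mask) else NULL
        powerStats[[paste(reg, bandName, sep = "_")]] <-
          list(F = f, posthoc = post)
      }
    }
    log$tfr <- tc
  }

  say("comodulograms")
  pairs <- simCfg$couplingWindows
  amp <- config$cfc$ampFreqs
  amp <- amp[amp >= config$stats$ampBand[1] & amp <= config$stats$ampBand[2]]
  comods <- lapply(cohort$roi, pathwayComodulograms, pairs = pairs,
                   phaseFreqs = config$cfc$phaseFreqs, ampFreqs = amp,
                   estimator = config$cfc$estimator)
  log$cfc <- list(phaseFreqs = config$cfc$phaseFreqs, ampFreqs = amp)

  subjects <- cohort$subjects
  isNR <- subjects$group == "non_responder"
  isR <- subjects$group == "responder"
  clusterTests <- list()
  features <- list()
  say("cluster permutation tests")
  for (w in seq_len(nrow(pairs))) {
    nm <- names(comods[[1]])[w]
    cw <- lapply(comods, `[[`, w)
    ct <- clusterPermutation(cw[isNR], cw[isR], P = config$stats$P,
                             clusterAlpha = config$stats$clusterAlpha,
                             connectivity = config$stats$connectivity,
                             seed = substreamSeed(config$seed, 50000 + w))
    clusterTests[[nm]] <- ct
    neg <- which(ct@clusterSigns == "negative")
    sig <- neg[ct@pValues[neg] < 0.05]
    if (length(neg)) {
      pick <- if (length(sig)) sig[which.max(abs(ct@clusterMasses[sig]))]
              else neg[which.max(abs(ct@clusterMasses[neg]))]
      mask <- ct@clusterMasks[[pick]]
      p <- ct@pValues[pick]
    } else {
      mask <- which(ct@statMap < 0)  # no suprathreshold cluster: fall back
      p <- NA_real_                  # to all negatively-shifted bins
    }
    if (length(mask))
      features[[nm]] <- list(
        mask = mask, significant = length(sig) > 0, p = p,
        strength = vapply(cw, clusterMeanStrength, numeric(1), mask = mask))
  }
  log$stats <- config$stats

  result <- list(config = config, subjects = subjects,
                 powerStats = powerStats, clusterTests = clusterTests,
                 features = features, stages = log)
  fnames <- names(features)
  for (nm in fnames) subjects[[paste0("strength_", nm)]] <-
    features[[nm]]$strength
  result$subjects <- subjects

  if (length(fnames) >= 1) {
    pat <- isNR | isR
    fm <- vapply(fnames, function(nm) features[[nm]]$strength[pat],
                 numeric(sum(pat)))
    colnames(fm) <- fnames
    result$correlations <- correlateFeatures(fm,
                                             subjects$reductionRatio[pat])
  }
  if (length(fnames) >= 2) {
    pat <- isNR | isR
    result$roc <- combineAndRoc(features[[1]]$strength[pat],
                                features[[2]]$strength[pat],
                                subjects$group[pat])
  }
  result$demographics <- demographicsTable(subjects)
  if (!is.null(config$outDir)) .writeRunOutputs(result, config$outDir)
  class(result) <- "PipelineRun"
  result
}

## Persist the run as open CSV formats so any stage is independently
## inspectable.
.writeRunOutputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(result$subjects, file.path(dir, "subjects.csv"),
            row.names = FALSE)
  cl <- do.call(rbind, lapply(names(result$clusterTests), function(nm) {
    ct <- result$clusterTests[[nm]]
    if (length(ct@clusterMasks) == 0) return(NULL)
    data.frame(pairWindow = nm, cluster = seq_along(ct@clusterMasks),
               sign = ct@clusterSigns, mass = ct@clusterMasses,
               p = ct@pValues,
               nBins = vapply(ct@clusterMasks, length, integer(1)))
  }))
  if (!is.null(cl))
    write.csv(cl, file.path(dir, "clusters.csv"), row.names = FALSE)
  if (!is.null(result$correlations))
    write.csv(result$correlations, file.path(dir, "correlations.csv"),
              row.names = FALSE)
  if (!is.null(result$roc)) {
    r <- result$roc$combined
    write.csv(data.frame(fpr = r@fpr, tpr = r@tpr,
                         threshold = r@thresholds),
              file.path(dir, "roc_curve.csv"), row.names = FALSE)
  }
  invisible(NULL)
}

#' @export
print.PipelineRun <- function(x, ...) {
  cat("PipelineRun:", nrow(x$subjects), "subjects\n")
  print(table(x$subjects$group))
  for (nm in names(x$clusterTests)) {
    cat("\n", nm, ":\n", sep = "")
    show(x$clusterTests[[nm]])
  }
  if (!is.null(x$correlations)) {
    cat("\nfeature-ratio correlations:\n")
    print(x$correlations)
  }
  if (!is.null(x$roc)) show(x$roc$combined)
  invisible(x)
}
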