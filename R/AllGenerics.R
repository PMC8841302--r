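#' @include AllClasses.R
NULL

#' Accessors for epoched series and results
#'
#' `seriesData()` returns the raw trials x channels x samples array;
#' `samplingRate()` the sampling frequency in Hz; `timeOnset()` the time of
#' the first sample relative to stimulus onset; `timeAxis()` the per-sample
#' time vector; `nTrials()`/`nSamples()` the tensor sizes; `seriesLabels()`
#' the channel or region names.
#'
#' @param x A [TimeSeriesArray-class] derivative.
#' @return See the individual descriptions.
#' @name series-accessors
#' @aliases seriesData samplingRate timeOnset timeAxis nTrials nSamples
#'   seriesLabels
NULL

#' @rdname series-accessors
#' @export
setGeneric("seriesData", function(x) standardGeneric("seriesData"))
#' @rdname series-accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname series-accessors
#' @export
setGeneric("timeOnset", function(x) standardGeneric("timeOnset"))
#' @rdname series-accessors
#' @export
setGeneric("timeAxis", function(x) standardGeneric("timeAxis"))
#' @rdname series-accessors
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))
#' @rdname series-accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname series-accessors
#' @export
setGeneric("seriesLabels", function(x) standardGeneric("seriesLabels"))

#' @rdname series-accessors
setMethod("seriesData", "TimeSeriesArray", function(x) x@data)
#' @rdname series-accessors
setMethod("samplingRate", "TimeSeriesArray", function(x) x@fs)
#' @rdname series-accessors
setMethod("timeOnset", "TimeSeriesArray", function(x) x@t0)
#' @rdname series-accessors
setMethod("timeAxis", "TimeSeriesArray", function(x)
  x@t0 + (seq_len(dim(x@data)[3L]) - 1L) / x@fs)
#' @rdname series-accessors
setMethod("nTrials", "TimeSeriesArray", function(x) dim(x@data)[1L])
#' @rdname series-accessors
setMethod("nSamples", "TimeSeriesArray", function(x) dim(x@data)[3L])
#' @rdname series-accessors
setMethod("seriesLabels", "EpochedSeries", function(x) x@channelLabels)
#' @rdname series-accessors
setMethod("seriesLabels", "RoiSeries", function(x) x@regionLabels)

#' Comodulogram accessors
#'
#' @param x A [Comodulogram-class].
#' @return `couplingValues()` the phase x amplitude coherence matrix with
#'   dimnames set from the grids; `phaseFreqs()`/`ampFreqs()` the Hz grids.
#' @name comodulogram-accessors
NULL

#' @rdname comodulogram-accessors
#' @export
setGeneric("couplingValues", function(x) standardGeneric("couplingValues"))
#' @rdname comodulogram-accessors
#' @export
setGeneric("phaseFreqs", function(x) standardGeneric("phaseFreqs"))
#' @rdname comodulogram-accessors
#' @export
setGeneric("ampFreqs", function(x) standardGeneric("ampFreqs"))

#' @rdname comodulogram-accessors
setMethod("couplingValues", "Comodulogram", function(x) {
  v <- x@values
  dimnames(v) <- list(phase = as.character(x@phaseFreqs),
                      amp = as.character(x@ampFreqs))
  v
})
#' @rdname comodulogram-accessors
setMethod("phaseFreqs", "Comodulogram", function(x) x@phaseFreqs)
#' @rdname comodulogram-accessors
setMethod("ampFreqs", "Comodulogram", function(x) x@ampFreqs)

setMethod("show", "EpochedSeries", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "EpochedSeries: %d trials x %d channels x %d samples @ %g Hz (t0 = %g s)\n",
    d[1L], d[2L], d[3L], object@fs, object@t0))
  cat("channels:", paste(head(object@channelLabels, 8L), collapse = ", "),
      if (d[2L] > 8L) "..." else "", "\n")
})

setMethod("show", "RoiSeries", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "RoiSeries: %d trials x %d regions x %d samples @ %g Hz (t0 = %g s)\n",
    d[1L], d[2L], d[3L], object@fs, object@t0))
  cat("regions:", paste(object@regionLabels, collapse = ", "), "\n")
})

setMethod("show", "Comodulogram", function(object) {
  cat(sprintf(
    "Comodulogram %s(phase) -> %s(envelope), window %g-%g ms, %d trials\n",
    object@phaseRegion, object@ampRegion, 1000 * object@window[1L],
    1000 * object@window[2L], object@nTrialsUsed))
  cat(sprintf("  %d phase bins (%g-%g Hz) x %d amplitude bins (%g-%g Hz)\n",
              length(object@phaseFreqs), min(object@phaseFreqs),
              max(object@phaseFreqs), length(object@ampFreqs),
              min(object@ampFreqs), max(object@ampFreqs)))
  i <- which(object@values == max(object@values), arr.ind = TRUE)[1L, ]
  cat(sprintf("  max value %.4f at (%g Hz, %g Hz)\n", max(object@values),
              object@phaseFreqs[i[1L]], object@ampFreqs[i[2L]]))
})

setMethod("show", "ClusterTestResult", function(object) {
  cat(sprintf("ClusterTestResult: %d x %d stat map, %d permutations\n",
              nrow(object@statMap), ncol(object@statMap),
              length(object@nullMaxMasses)))
  if (length(object@clusterMasks) == 0L) {
    cat("  no suprathreshold clusters\n")
  } else {
    for (i in seq_along(object@clusterMasks))
      cat(sprintf("  cluster %d: %s, %d bins, mass %.2f, p = %.4g\n", i,
                  object@clusterSigns[i], length(object@clusterMasks[[i]]),
                  object@clusterMasses[i], object@pValues[i]))
  }
})

setMethod("show", "RocResult", function(object) {
  cat(sprintf(
    "RocResult: AUC = %.3f; Youden point sens = %.3f, spec = %.3f @ %.4g\n",
    object@auc, object@sensitivity, object@specificity, object@threshold))
})

setMethod("show", "CohortCounts", function(object) {
  cat("CohortCounts\n")
  cat(sprintf("  enrolled: %d MDD + %d HC\n", object@enrolledMdd,
              object@enrolledHc))
  cat(sprintf("  excluded: %d ECT, %d MDD quality, %d HC quality, %d switch\n",
              object@excludedEct, object@excludedQualityMdd,
              object@excludedQualityHc, object@excludedSwitch))
  cat(sprintf("  analyzed: %d MDD + %d HC = %d\n", object@remainingMdd,
              object@remainingHc, object@analyzedTotal))
})
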