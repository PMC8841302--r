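#' @include megpac-package.R
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))
setClassUnion("matrixOrNULL", c("matrix", "NULL"))

## ---------------------------------------------------------------------------
## Epoched time-series containers
## ---------------------------------------------------------------------------

.validTimeSeriesArray <- function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L)
    msg <- c(msg, "'data' must be a 3-D array [trials x channels x samples]")
  if (!all(is.finite(object@data)))
    msg <- c(msg, "'data' must be finite everywhere")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "'fs' must be a single positive number")
  if (length(object@t0) != 1L || !is.finite(object@t0))
    msg <- c(msg, "'t0' must be a single finite number")
  if (length(msg)) msg else TRUE
}

#' Virtual parent of epoched sensor- and source-level series
#'
#' Holds a trials x channels x samples tensor, the sampling rate, and the
#' time of the first sample relative to stimulus onset.
#'
#' @slot data 3-D numeric array, trials x channels x samples.
#' @slot fs Sampling rate in Hz.
#' @slot t0 Time of the first sample in seconds relative to stimulus onset
#'   (negative for pre-stimulus padding).
#' @exportClass TimeSeriesArray
setClass("TimeSeriesArray",
  representation("VIRTUAL", data = "array", fs = "numeric", t0 = "numeric"),
  validity = .validTimeSeriesArray)

#' Epoched sensor-level MEG series
#'
#' @slot channelLabels Unique channel names, one per channel dimension entry.
#' @seealso [epochedSeries()] for the constructor.
#' @exportClass EpochedSeries
setClass("EpochedSeries", contains = "TimeSeriesArray",
  representation(channelLabels = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@channelLabels) != dim(object@data)[2L])
      msg <- c(msg, "one channel label per channel required")
    if (anyDuplicated(object@channelLabels))
      msg <- c(msg, "channel labels must be unique")
    if (length(msg)) msg else TRUE
  })

#' Epoched source-level (region-of-interest) series
#'
#' @slot regionLabels Unique region names, one per region dimension entry.
#' @seealso [roiSeries()] for the constructor.
#' @exportClass RoiSeries
setClass("RoiSeries", contains = "TimeSeriesArray",
  representation(regionLabels = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@regionLabels) != dim(object@data)[2L])
      msg <- c(msg, "one region label per region required")
    if (anyDuplicated(object@regionLabels))
      msg <- c(msg, "region labels must be unique")
    if (length(msg)) msg else TRUE
  })

#' Construct an epoched sensor-level series
#'
#' @param data 3-D array, trials x channels x samples.
#' @param fs Sampling rate (Hz).
#' @param t0 Time of the first sample relative to stimulus onset (s).
#' @param channelLabels Channel names; default `ch1, ch2, ...`.
#' @return An [EpochedSeries-class] object.
#' @export
epochedSeries <- function(data, fs, t0 = 0,
                          channelLabels = paste0("ch", seq_len(dim(data)[2L]))) {
  new("EpochedSeries", data = data, fs = fs, t0 = t0,
      channelLabels = as.character(channelLabels))
}

#' Construct an epoched region-of-interest series
#'
#' @inheritParams epochedSeries
#' @param regionLabels Region names.
#' @return A [RoiSeries-class] object.
#' @export
roiSeries <- function(data, fs, t0 = 0,
                      regionLabels = paste0("roi", seq_len(dim(data)[2L]))) {
  new("RoiSeries", data = data, fs = fs, t0 = t0,
      regionLabels = as.character(regionLabels))
}

## ---------------------------------------------------------------------------
## Forward model and spatial filters
## ---------------------------------------------------------------------------

#' Toy lead field for a fixed-orientation source grid
#'
#' Linear forward mapping from abstract sources to sensors, plus the
#' assignment of sources to regions of interest. Stands in for an anatomical
#' head model: only the algebra of source reconstruction is represented.
#'
#' @slot gain Sensors x sources gain matrix (fixed orientation).
#' @slot roiMap Character vector, length = number of sources, naming the ROI
#'   owning each source.
#' @slot positions Optional sources x 3 coordinate matrix (arbitrary units).
#' @seealso [toyLeadField()] for a randomized constructor.
#' @exportClass ToyLeadField
setClass("ToyLeadField",
  representation(gain = "matrix", roiMap = "character",
                 positions = "matrixOrNULL"),
  prototype(positions = NULL),
  validity = function(object) {
    msg <- character()
    if (length(object@roiMap) != ncol(object@gain))
      msg <- c(msg, "'roiMap' must name one ROI per gain column")
    if (ncol(object@gain) > 0 &&
        qr(object@gain)$rank < ncol(object@gain))
      msg <- c(msg, "'gain' must have full column rank")
    if (any(colSums(abs(object@gain)) == 0))
      msg <- c(msg, "zero lead-field column")
    if (length(msg)) msg else TRUE
  })

#' LCMV spatial filter set
#'
#' Rows of `weights` map sensors to unit-gain source estimates:
#' `weights[s, ] %*% gain[, s] == 1` for every source `s`.
#'
#' @slot weights Sources x sensors weight matrix.
#' @slot regularization Diagonal loading used, as a fraction of the mean
#'   sensor variance.
#' @slot covWindow Covariance estimation window (start, end) in seconds, or
#'   `NULL` when the whole epoch was used.
#' @exportClass SpatialFilterSet
setClass("SpatialFilterSet",
  representation(weights = "matrix", regularization = "numeric",
                 covWindow = "numericOrNULL"),
  prototype(covWindow = NULL))

## ---------------------------------------------------------------------------
## Spectral and coupling results
## ---------------------------------------------------------------------------

#' Time-frequency power representation
#'
#' Trial-averaged power for each region on a frequency x time grid. Bins whose
#' analysis window does not fit inside the epoch are `NA` (missing, never
#' zero-imputed).
#'
#' @slot power Regions x frequencies x time-bins array (>= 0 or NA).
#' @slot freqs Frequency grid (Hz), strictly increasing.
#' @slot times Time-bin centers (s).
#' @slot regionLabels Region names.
#' @slot method Estimator tag per frequency: `"hanning"` or `"multitaper"`.
#' @exportClass TimeFreqPower
setClass("TimeFreqPower",
  representation(power = "array", freqs = "numeric", times = "numeric",
                 regionLabels = "character", method = "character"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@power)
    if (length(d) != 3L)
      msg <- c(msg, "'power' must be regions x freqs x times")
    else {
      if (d[2L] != length(object@freqs) || d[3L] != length(object@times))
        msg <- c(msg, "grid lengths must match 'power' dimensions")
      if (d[1L] != length(object@regionLabels))
        msg <- c(msg, "one region label per power row required")
    }
    if (is.unsorted(object@freqs, strictly = TRUE))
      msg <- c(msg, "'freqs' must be strictly increasing")
    if (any(object@power < 0, na.rm = TRUE))
      msg <- c(msg, "power must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' Cross-regional phase-amplitude comodulogram
#'
#' Phasor-envelope coherence on a (phase frequency, amplitude frequency)
#' grid, for one (phase region, amplitude region, time window) triple.
#'
#' @slot values Phase-bins x amplitude-bins matrix of coherence values in
#'   [0, 1].
#' @slot phaseFreqs,ampFreqs Hz grids, strictly increasing.
#' @slot window Analysis window (start, end) in seconds after stimulus onset.
#' @slot phaseRegion,ampRegion ROI labels providing the slow phase and the
#'   fast envelope.
#' @slot nTrialsUsed Number of trials pooled into the estimate.
#' @exportClass Comodulogram
setClass("Comodulogram",
  representation(values = "matrix", phaseFreqs = "numeric",
                 ampFreqs = "numeric", window = "numeric",
                 phaseRegion = "character", ampRegion = "character",
                 nTrialsUsed = "integer"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@values) != length(object@phaseFreqs) ||
        ncol(object@values) != length(object@ampFreqs))
      msg <- c(msg, "'values' shape must match the frequency grids")
    if (is.unsorted(object@phaseFreqs, strictly = TRUE) ||
        is.unsorted(object@ampFreqs, strictly = TRUE))
      msg <- c(msg, "frequency grids must be strictly increasing")
    if (any(object@values < -1e-12 | object@values > 1 + 1e-12, na.rm = TRUE))
      msg <- c(msg, "coherence values must lie in [0, 1]")
    if (length(object@window) != 2L || diff(object@window) <= 0)
      msg <- c(msg, "'window' must be (start, end) with end > start")
    if (length(msg)) msg else TRUE
  })

#' Cluster-based permutation test result
#'
#' @slot statMap Per-bin two-sample t map (groups A - B).
#' @slot clusterMasks List of integer index vectors into `statMap`, one per
#'   cluster (disjoint).
#' @slot clusterMasses Sum of t over each cluster's bins.
#' @slot clusterSigns `"positive"` or `"negative"` per cluster.
#' @slot nullMaxMasses Permutation null: max absolute cluster mass per
#'   shuffle (length = number of permutations).
#' @slot pValues Permutation p-value per cluster, in [1/(P+1), 1].
#' @slot clusterAlpha Two-sided cluster-forming alpha.
#' @slot phaseFreqs,ampFreqs Grids the map lives on.
#' @exportClass ClusterTestResult
setClass("ClusterTestResult",
  representation(statMap = "matrix", clusterMasks = "list",
                 clusterMasses = "numeric", clusterSigns = "character",
                 nullMaxMasses = "numeric", pValues = "numeric",
                 clusterAlpha = "numeric", phaseFreqs = "numeric",
                 ampFreqs = "numeric"),
  validity = function(object) {
    msg <- character()
    k <- length(object@clusterMasks)
    if (length(object@clusterMasses) != k || length(object@pValues) != k ||
        length(object@clusterSigns) != k)
      msg <- c(msg, "per-cluster slots must have equal length")
    if (k > 1 && anyDuplicated(unlist(object@clusterMasks)))
      msg <- c(msg, "cluster masks must be disjoint")
    P <- length(object@nullMaxMasses)
    if (k > 0 && P > 0 &&
        any(object@pValues < 1 / (P + 1) - 1e-12 | object@pValues > 1 + 1e-12))
      msg <- c(msg, "p-values must lie in [1/(P+1), 1]")
    if (length(msg)) msg else TRUE
  })

#' ROC analysis result
#'
#' @slot auc Trapezoidal area under the stored curve.
#' @slot fpr,tpr,thresholds ROC curve points (monotone in both coordinates).
#' @slot sensitivity,specificity,threshold Operating point maximizing
#'   Youden's J = sensitivity + specificity - 1.
#' @slot coefficients Linear-combiner coefficients (intercept + features), or
#'   a single NA for a raw single-feature score.
#' @exportClass RocResult
setClass("RocResult",
  representation(auc = "numeric", fpr = "numeric", tpr = "numeric",
                 thresholds = "numeric", sensitivity = "numeric",
                 specificity = "numeric", threshold = "numeric",
                 coefficients = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@auc < -1e-12 || object@auc > 1 + 1e-12)
      msg <- c(msg, "'auc' must lie in [0, 1]")
    if (is.unsorted(object@fpr) || is.unsorted(object@tpr))
      msg <- c(msg, "ROC curve must be monotone non-decreasing")
    if (length(msg)) msg else TRUE
  })

#' Cohort exclusion-cascade arithmetic
#'
#' @slot enrolledMdd,enrolledHc Enrollment counts.
#' @slot excludedEct,excludedQualityMdd,excludedQualityHc,excludedSwitch
#'   Exclusion counts (electroconvulsive therapy, data quality, treatment
#'   switch).
#' @slot remainingMdd,remainingHc,analyzedTotal Derived counts.
#' @seealso [exclusionCascade()]
#' @exportClass CohortCounts
setClass("CohortCounts",
  representation(enrolledMdd = "integer", enrolledHc = "integer",
                 excludedEct = "integer", excludedQualityMdd = "integer",
                 excludedQualityHc = "integer", excludedSwitch = "integer",
                 remainingMdd = "integer", remainingHc = "integer",
                 analyzedTotal = "integer"),
  validity = function(object) {
    msg <- character()
    counts <- c(object@enrolledMdd, object@enrolledHc, object@excludedEct,
                object@excludedQualityMdd, object@excludedQualityHc,
                object@excludedSwitch, object@remainingMdd,
                object@remainingHc, object@analyzedTotal)
    if (any(counts < 0))
      msg <- c(msg, "all counts must be non-negative")
    if (object@remainingMdd != object@enrolledMdd - object@excludedEct -
        object@excludedQualityMdd - object@excludedSwitch)
      msg <- c(msg, "remainingMdd arithmetic violated")
    if (object@remainingHc != object@enrolledHc - object@excludedQualityHc)
      msg <- c(msg, "remainingHc arithmetic violated")
    if (object@analyzedTotal != object@remainingMdd + object@remainingHc)
      msg <- c(msg, "analyzedTotal arithmetic violated")
    if (length(msg)) msg else TRUE
  })
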