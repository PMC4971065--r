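#' @import methods
NULL

#' Electrode montage
#'
#' Channel identities and 2-D scalp positions (unitless, head seen from above,
#' nose up: positive y is anterior, positive x is the subject's right).
#'
#' @slot channelNames character vector of unique channel labels.
#' @slot positions numeric matrix with one row per channel and columns
#'   \code{x}, \code{y}.
#'
#' @seealso [readMontage()], [standardMontage()]
#' @exportClass Montage
setClass("Montage",
  representation(channelNames = "character", positions = "matrix"),
  validity = function(object) {
    msg <- character(0)
    n <- length(object@channelNames)
    if (n < 2L) msg <- c(msg, "a montage needs at least 2 channels")
    if (anyDuplicated(object@channelNames))
      msg <- c(msg, "channel names must be unique")
    if (nrow(object@positions) != n || ncol(object@positions) != 2L)
      msg <- c(msg, "'positions' must be an n x 2 matrix")
    if (!all(is.finite(object@positions)))
      msg <- c(msg, "positions must be finite")
    if (length(msg)) msg else TRUE
  })

#' Multichannel EEG recording
#'
#' A channels x samples matrix (microvolts) together with its sampling rate
#' and subject metadata. Rows follow the montage channel order.
#'
#' @slot data numeric matrix, channels x samples.
#' @slot fs sampling rate in Hz.
#' @slot subjectId subject label.
#' @slot group group label, e.g. \code{"patient"} or \code{"control"}.
#' @slot montage a [Montage-class].
#'
#' @exportClass EEGRecording
setClass("EEGRecording",
  representation(data = "matrix", fs = "numeric", subjectId = "character",
                 group = "character", montage = "Montage"),
  validity = function(object) {
    msg <- character(0)
    if (nrow(object@data) != length(object@montage@channelNames))
      msg <- c(msg, "data row count must equal montage channel count")
    if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
      msg <- c(msg, "fs must be a single positive number")
    if (!all(is.finite(object@data)))
      msg <- c(msg, "data values must be finite")
    if (length(msg)) msg else TRUE
  })

#' Microstate template set
#'
#' K microstate topographies, one per row, each average-referenced (zero mean
#' across channels) and unit-norm, with unique class labels (canonically
#' "A", "B", "C", "D", ...).
#'
#' @slot maps numeric matrix, K x channels.
#' @slot labels character vector of K unique class labels.
#'
#' @exportClass TemplateSet
setClass("TemplateSet",
  representation(maps = "matrix", labels = "character"),
  validity = function(object) {
    msg <- character(0)
    K <- nrow(object@maps)
    if (length(object@labels) != K) msg <- c(msg, "one label per template")
    if (anyDuplicated(object@labels)) msg <- c(msg, "labels must be unique")
    if (K > 0) {
      if (max(abs(rowMeans(object@maps))) > 1e-8)
        msg <- c(msg, "template rows must be average-referenced (mean 0)")
      if (max(abs(sqrt(rowSums(object@maps^2)) - 1)) > 1e-8)
        msg <- c(msg, "template rows must have unit norm")
    }
    if (length(msg)) msg else TRUE
  })

#' Global field power series
#'
#' Per-sample GFP (the population standard deviation across channels of the
#' average-referenced topography) plus the retained and excluded local-maximum
#' indices.
#'
#' @slot values numeric vector of per-sample GFP (microvolts), all >= 0.
#' @slot peakIndices strictly increasing sample indices of retained peaks.
#' @slot excludedPeakIndices indices of peaks removed by the amplitude
#'   outlier rule.
#' @slot fs sampling rate in Hz.
#'
#' @exportClass GFPSeries
setClass("GFPSeries",
  representation(values = "numeric", peakIndices = "integer",
                 excludedPeakIndices = "integer", fs = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (any(object@values < 0)) msg <- c(msg, "GFP values must be >= 0")
    if (is.unsorted(object@peakIndices, strictly = TRUE))
      msg <- c(msg, "peak indices must be strictly increasing")
    if (length(intersect(object@peakIndices, object@excludedPeakIndices)))
      msg <- c(msg, "retained and excluded peaks must be disjoint")
    if (length(msg)) msg else TRUE
  })

#' Set of peak topographies
#'
#' Average-referenced maps extracted at retained GFP peaks, in temporal
#' order, one row per peak.
#'
#' @slot maps numeric matrix, peaks x channels, rows mean 0.
#' @slot sourceIndices originating sample index of each map.
#' @slot subjectId subject label ("" for concatenated sets).
#'
#' @exportClass TopographySet
setClass("TopographySet",
  representation(maps = "matrix", sourceIndices = "integer",
                 subjectId = "character"),
  validity = function(object) {
    msg <- character(0)
    if (nrow(object@maps) != length(object@sourceIndices))
      msg <- c(msg, "one source index per map")
    if (nrow(object@maps) > 0 && max(abs(rowMeans(object@maps))) > 1e-9)
      msg <- c(msg, "maps must be average-referenced (row mean <= 1e-9)")
    if (length(msg)) msg else TRUE
  })

#' Result of modified K-means clustering
#'
#' @slot templates the fitted [TemplateSet-class].
#' @slot assignments per-peak template index (1..K).
#' @slot polarity per-peak sign (+1/-1) of the winning spatial correlation.
#' @slot gevTotal total global explained variance in [0, 1].
#' @slot gevPerTemplate per-template GEV; sums to \code{gevTotal}.
#' @slot cvCriterion predictive residual-variance criterion for this K.
#' @slot nIterations iterations used by the best restart.
#' @slot converged TRUE if the best restart converged before the iteration cap.
#'
#' @exportClass ClusteringResult
setClass("ClusteringResult",
  representation(templates = "TemplateSet", assignments = "integer",
                 polarity = "numeric", gevTotal = "numeric",
                 gevPerTemplate = "numeric", cvCriterion = "numeric",
                 nIterations = "integer", converged = "logical"),
  validity = function(object) {
    msg <- character(0)
    if (object@gevTotal < 0 || object@gevTotal > 1 + 1e-12)
      msg <- c(msg, "gevTotal must lie in [0, 1]")
    if (abs(sum(object@gevPerTemplate) - object@gevTotal) > 1e-9)
      msg <- c(msg, "per-template GEV must sum to gevTotal")
    if (any(object@assignments < 1L) ||
        any(object@assignments > nrow(object@templates@maps)))
      msg <- c(msg, "every peak must be assigned to an existing template")
    if (length(msg)) msg else TRUE
  })

#' Microstate segmentation of a continuous recording
#'
#' Per-sample microstate labels obtained by competitive backfitting, plus the
#' absolute spatial correlation to the winning template.
#'
#' @slot labels integer vector, one state index (1..K) per sample.
#' @slot corr per-sample |spatial correlation| to the winning template.
#' @slot stateNames the K state labels, in index order.
#' @slot fs sampling rate in Hz.
#' @slot subjectId subject label.
#'
#' @exportClass Segmentation
setClass("Segmentation",
  representation(labels = "integer", corr = "numeric", stateNames = "character",
                 fs = "numeric", subjectId = "character"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@labels) != length(object@corr))
      msg <- c(msg, "labels and corr must have equal length")
    if (length(object@corr) &&
        (min(object@corr) < -1e-12 || max(object@corr) > 1 + 1e-12))
      msg <- c(msg, "corr must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' Per-subject temporal microstate parameters
#'
#' @slot stats data.frame with one row per state: \code{state},
#'   \code{mean_duration_ms}, \code{occurrence_per_s}, \code{ratio_total_time},
#'   \code{gev}, \code{visited}.
#' @slot transitionMatrix K x K row-stochastic sample-to-sample transition
#'   matrix, diagonal (self-transitions) included.
#' @slot transitionMatrixRuns K x K run-level transition matrix
#'   (self-transitions excluded, zero diagonal), for comparability with
#'   literature that reports run-wise transitions.
#' @slot subjectId subject label.
#' @slot group group label.
#'
#' @exportClass MicrostateMetrics
setClass("MicrostateMetrics",
  representation(stats = "data.frame", transitionMatrix = "matrix",
                 transitionMatrixRuns = "matrix", subjectId = "character",
                 group = "character"),
  validity = function(object) {
    msg <- character(0)
    need <- c("state", "mean_duration_ms", "occurrence_per_s",
              "ratio_total_time", "gev", "visited")
    if (!all(need %in% names(object@stats)))
      msg <- c(msg, "stats is missing required columns")
    if (abs(sum(object@stats$ratio_total_time) - 1) > 1e-9)
      msg <- c(msg, "ratio_total_time must sum to 1")
    rs <- rowSums(object@transitionMatrix)
    if (any(abs(rs[rs > 0] - 1) > 1e-9))
      msg <- c(msg, "transition rows must sum to 1 (or 0 for unvisited states)")
    if (length(msg)) msg else TRUE
  })

#' RSN component time courses for one subject
#'
#' @slot timecourses numeric matrix, components x volumes.
#' @slot trS repetition time in seconds.
#' @slot componentNames component labels.
#' @slot subjectId subject label.
#'
#' @exportClass RSNTimecourseSet
setClass("RSNTimecourseSet",
  representation(timecourses = "matrix", trS = "numeric",
                 componentNames = "character", subjectId = "character"),
  validity = function(object) {
    msg <- character(0)
    if (!all(is.finite(object@timecourses)))
      msg <- c(msg, "time courses must be finite")
    if (ncol(object@timecourses) < 10L)
      msg <- c(msg, "need at least 10 volumes")
    if (nrow(object@timecourses) != length(object@componentNames))
      msg <- c(msg, "one name per component")
    if (length(object@trS) != 1L || object@trS <= 0)
      msg <- c(msg, "trS must be a single positive number")
    if (length(msg)) msg else TRUE
  })

#' Result of microstate-to-RSN temporal sorting
#'
#' Per-subject regression slopes of RSN component time courses on
#' HRF-convolved microstate regressors, group-mean slopes, and Z maps
#' standardized across components within each (microstate, group) cell.
#'
#' @slot slopes 3-D array: subjects x microstates x components.
#' @slot groupMeanSlopes named list (one per group) of
#'   microstates x components mean-slope matrices.
#' @slot zMap named list (one per group) of microstates x components Z
#'   matrices; each row has mean 0 and unit variance across components
#'   (all-zero when the row is degenerate).
#' @slot flagged data.frame of pairings with Z >= 1 (columns \code{group},
#'   \code{state}, \code{component}, \code{z}).
#'
#' @exportClass SortingResult
setClass("SortingResult",
  representation(slopes = "array", groupMeanSlopes = "list", zMap = "list",
                 flagged = "data.frame"),
  validity = function(object) {
    msg <- character(0)
    for (g in names(object@zMap)) {
      z <- object@zMap[[g]]
      for (i in seq_len(nrow(z))) {
        zi <- z[i, ]
        if (any(zi != 0)) {
          if (abs(mean(zi)) > 1e-9 || abs(stats::var(zi) - 1) > 1e-9)
            msg <- c(msg, "non-degenerate z rows must be standardized")
        }
      }
    }
    if (length(msg)) msg else TRUE
  })
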