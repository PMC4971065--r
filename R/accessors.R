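#' Accessors for the core classes
#'
#' Small accessor functions returning slot contents; use these rather than
#' reaching into slots directly.
#'
#' @param x an object of one of the package classes.
#' @param ... further arguments (see individual methods).
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
setMethod("nChannels", "Montage", function(x) length(x@channelNames))
#' @rdname accessors
setMethod("nChannels", "EEGRecording", function(x) nrow(x@data))
#' @rdname accessors
setMethod("nChannels", "TemplateSet", function(x) ncol(x@maps))

#' @rdname accessors
setMethod("channelNames", "Montage", function(x) x@channelNames)
#' @rdname accessors
setMethod("channelNames", "EEGRecording", function(x) x@montage@channelNames)

#' @rdname accessors
setMethod("samplingRate", "EEGRecording", function(x) x@fs)
#' @rdname accessors
setMethod("samplingRate", "GFPSeries", function(x) x@fs)
#' @rdname accessors
setMethod("samplingRate", "Segmentation", function(x) x@fs)

#' @rdname accessors
setMethod("maps", "TemplateSet", function(x) x@maps)
#' @rdname accessors
setMethod("maps", "TopographySet", function(x) x@maps)

#' @rdname accessors
setMethod("stateLabels", "TemplateSet", function(x) x@labels)
#' @rdname accessors
setMethod("stateLabels", "Segmentation", function(x) x@stateNames)

#' @rdname accessors
setMethod("subjectId", "EEGRecording", function(x) x@subjectId)
#' @rdname accessors
setMethod("subjectId", "Segmentation", function(x) x@subjectId)
#' @rdname accessors
setMethod("subjectId", "TopographySet", function(x) x@subjectId)
#' @rdname accessors
setMethod("subjectId", "MicrostateMetrics", function(x) x@subjectId)
#' @rdname accessors
setMethod("subjectId", "RSNTimecourseSet", function(x) x@subjectId)

#' @rdname accessors
setMethod("subjectGroup", "EEGRecording", function(x) x@group)
#' @rdname accessors
setMethod("subjectGroup", "MicrostateMetrics", function(x) x@group)

#' @rdname accessors
setMethod("eegData", "EEGRecording", function(x) x@data)

#' @rdname accessors
setMethod("gfpValues", "GFPSeries", function(x) x@values)
#' @rdname accessors
setMethod("peakIndices", "GFPSeries", function(x) x@peakIndices)
#' @rdname accessors
setMethod("excludedPeakIndices", "GFPSeries", function(x) x@excludedPeakIndices)

#' @rdname accessors
setMethod("sampleLabels", "Segmentation", function(x) x@labels)

#' @rdname accessors
setMethod("templates", "ClusteringResult", function(x) x@templates)
#' @rdname accessors
setMethod("gevTotal", "ClusteringResult", function(x) x@gevTotal)

#' @rdname accessors
setMethod("metricsStats", "MicrostateMetrics", function(x) x@stats)

#' @param level for \code{transitionMatrix}: \code{"sample"} (sample-to-sample,
#'   self-transitions on the diagonal) or \code{"run"} (run-level,
#'   self-transitions excluded).
#' @rdname accessors
setMethod("transitionMatrix", "MicrostateMetrics",
  function(x, level = c("sample", "run")) {
    level <- match.arg(level)
    if (level == "sample") x@transitionMatrix else x@transitionMatrixRuns
  })

setMethod("show", "Montage", function(object) {
  cat("Montage with", nChannels(object), "channels:",
      paste(utils::head(object@channelNames, 6), collapse = ", "),
      if (nChannels(object) > 6) "..." else "", "\n")
})

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording '%s' (%s): %d channels x %d samples @ %g Hz (%.1f s)\n",
              object@subjectId, object@group, nrow(object@data),
              ncol(object@data), object@fs, ncol(object@data) / object@fs))
})

setMethod("show", "TemplateSet", function(object) {
  cat(sprintf("TemplateSet: %d templates (%s) over %d channels\n",
              nrow(object@maps), paste(object@labels, collapse = ", "),
              ncol(object@maps)))
})

setMethod("show", "GFPSeries", function(object) {
  cat(sprintf("GFPSeries: %d samples @ %g Hz, %d retained peaks, %d excluded\n",
              length(object@values), object@fs, length(object@peakIndices),
              length(object@excludedPeakIndices)))
})

setMethod("show", "TopographySet", function(object) {
  cat(sprintf("TopographySet '%s': %d maps over %d channels\n",
              object@subjectId, nrow(object@maps), ncol(object@maps)))
})

setMethod("show", "ClusteringResult", function(object) {
  cat(sprintf(paste0("ClusteringResult: K=%d, GEV=%.4f, CV=%.5g, ",
                     "%d peaks, %d iterations (%s)\n"),
              nrow(object@templates@maps), object@gevTotal, object@cvCriterion,
              length(object@assignments), object@nIterations,
              if (object@converged) "converged" else "not converged"))
})

setMethod("show", "Segmentation", function(object) {
  cat(sprintf("Segmentation '%s': %d samples @ %g Hz into states {%s}\n",
              object@subjectId, length(object@labels), object@fs,
              paste(object@stateNames, collapse = ", ")))
})

setMethod("show", "MicrostateMetrics", function(object) {
  cat(sprintf("MicrostateMetrics '%s' (%s):\n", object@subjectId, object@group))
  print(object@stats, row.names = FALSE)
})

setMethod("show", "RSNTimecourseSet", function(object) {
  cat(sprintf("RSNTimecourseSet '%s': %d components x %d volumes, TR %g s\n",
              object@subjectId, nrow(object@timecourses),
              ncol(object@timecourses), object@trS))
})

setMethod("show", "SortingResult", function(object) {
  d <- dim(object@slopes)
  cat(sprintf("SortingResult: %d subjects x %d states x %d components; %d flagged pairings\n",
              d[1], d[2], d[3], nrow(object@flagged)))
})
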