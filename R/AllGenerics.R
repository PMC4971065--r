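#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("maps", function(x) standardGeneric("maps"))

#' @rdname accessors
#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))

#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname accessors
#' @export
setGeneric("subjectGroup", function(x) standardGeneric("subjectGroup"))

#' @rdname accessors
#' @export
setGeneric("eegData", function(x) standardGeneric("eegData"))

#' @rdname accessors
#' @export
setGeneric("gfpValues", function(x) standardGeneric("gfpValues"))

#' @rdname accessors
#' @export
setGeneric("peakIndices", function(x) standardGeneric("peakIndices"))

#' @rdname accessors
#' @export
setGeneric("excludedPeakIndices", function(x) standardGeneric("excludedPeakIndices"))

#' @rdname accessors
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))

#' @rdname accessors
#' @export
setGeneric("templates", function(x) standardGeneric("templates"))

#' @rdname accessors
#' @export
setGeneric("gevTotal", function(x) standardGeneric("gevTotal"))

#' @rdname accessors
#' @export
setGeneric("metricsStats", function(x) standardGeneric("metricsStats"))

#' @rdname accessors
#' @export
setGeneric("transitionMatrix", function(x, ...) standardGeneric("transitionMatrix"))
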