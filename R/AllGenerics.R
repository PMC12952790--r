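#' @include AllClasses.R
NULL

#' Accessors for quantaflux objects
#'
#' Small accessor generics following the usual Bioconductor idiom: slots are
#' never touched directly by user code.
#'
#' @param object a quantaflux S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frameRate", function(object) standardGeneric("frameRate"))
#' @rdname accessors
#' @export
setGeneric("frameInterval", function(object) standardGeneric("frameInterval"))
#' @rdname accessors
#' @export
setGeneric("startTime", function(object) standardGeneric("startTime"))
#' @rdname accessors
#' @export
setGeneric("roiId", function(object) standardGeneric("roiId"))
#' @rdname accessors
#' @export
setGeneric("acqMeta", function(object) standardGeneric("acqMeta"))
#' @rdname accessors
#' @export
setGeneric("signalValues", function(object) standardGeneric("signalValues"))
#' @rdname accessors
#' @export
setGeneric("referenceValues", function(object) standardGeneric("referenceValues"))
#' @rdname accessors
#' @export
setGeneric("hasReference", function(object) standardGeneric("hasReference"))
#' @rdname accessors
#' @export
setGeneric("traceMode", function(object) standardGeneric("traceMode"))
#' @rdname accessors
#' @export
setGeneric("timePoints", function(object) standardGeneric("timePoints"))
#' @rdname accessors
#' @export
setGeneric("traceValues", function(object) standardGeneric("traceValues"))
#' @rdname accessors
#' @export
setGeneric("baselineValues", function(object) standardGeneric("baselineValues"))
#' @rdname accessors
#' @export
setGeneric("rawValues", function(object) standardGeneric("rawValues"))
#' @rdname accessors
#' @export
setGeneric("normParams", function(object) standardGeneric("normParams"))
#' @rdname accessors
#' @export
setGeneric("blockLabels", function(object) standardGeneric("blockLabels"))
#' @rdname accessors
#' @export
setGeneric("blockFrequencies", function(object) standardGeneric("blockFrequencies"))
#' @rdname accessors
#' @export
setGeneric("stimulusTimes", function(object, block) standardGeneric("stimulusTimes"))
#' @rdname accessors
#' @export
setGeneric("nStimuli", function(object) standardGeneric("nStimuli"))
#' @rdname accessors
#' @export
setGeneric("matchedPairs", function(object) standardGeneric("matchedPairs"))
#' @rdname accessors
#' @export
setGeneric("unmatchedEphys", function(object) standardGeneric("unmatchedEphys"))
#' @rdname accessors
#' @export
setGeneric("unmatchedOptical", function(object) standardGeneric("unmatchedOptical"))
#' @rdname accessors
#' @export
setGeneric("matchTolerance", function(object) standardGeneric("matchTolerance"))
#' @rdname accessors
#' @export
setGeneric("azAmplitudes", function(object) standardGeneric("azAmplitudes"))
#' @rdname accessors
#' @export
setGeneric("azIds", function(object) standardGeneric("azIds"))
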