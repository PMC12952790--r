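#' @include AllGenerics.R
NULL

#' @rdname accessors
setMethod("frameRate", "AcquisitionMeta", function(object) object@frameRate)
#' @rdname accessors
setMethod("frameInterval", "AcquisitionMeta", function(object) 1000 / object@frameRate)
#' @rdname accessors
setMethod("startTime", "AcquisitionMeta", function(object) object@startTime)

for (cls in c("Recording", "NormalizedTrace")) {
  setMethod("frameRate", cls, function(object) object@meta@frameRate)
  setMethod("frameInterval", cls, function(object) 1000 / object@meta@frameRate)
  setMethod("startTime", cls, function(object) object@meta@startTime)
  setMethod("roiId", cls, function(object) object@roiId)
  setMethod("acqMeta", cls, function(object) object@meta)
}

#' @rdname accessors
setMethod("signalValues", "Recording", function(object) object@signal)
#' @rdname accessors
setMethod("referenceValues", "Recording", function(object) {
  if (!length(object@reference)) NULL else object@reference
})
#' @rdname accessors
setMethod("hasReference", "Recording", function(object) length(object@reference) > 0L)
#' @rdname accessors
setMethod("traceMode", "Recording", function(object) object@mode)
#' @rdname accessors
setMethod("traceMode", "NormalizedTrace", function(object) object@mode)

#' @rdname accessors
setMethod("timePoints", "Recording", function(object)
  object@meta@startTime + (seq_along(object@signal) - 1L) * frameInterval(object))
#' @rdname accessors
setMethod("timePoints", "NormalizedTrace", function(object)
  object@meta@startTime + (seq_along(object@values) - 1L) * frameInterval(object))

#' @rdname accessors
setMethod("traceValues", "NormalizedTrace", function(object) object@values)
#' @rdname accessors
setMethod("baselineValues", "NormalizedTrace", function(object) object@baseline)
#' @rdname accessors
setMethod("rawValues", "NormalizedTrace", function(object) object@raw)
#' @rdname accessors
setMethod("normParams", "NormalizedTrace", function(object) object@params)

#' @rdname accessors
setMethod("blockLabels", "StimulusProtocol", function(object) object@labels)
#' @rdname accessors
setMethod("blockFrequencies", "StimulusProtocol", function(object)
  setNames(object@frequencies, object@labels))
#' @rdname accessors
#' @param block block label; omit for all stimulus times pooled in order.
setMethod("stimulusTimes", "StimulusProtocol", function(object, block) {
  if (missing(block)) return(unlist(object@times, use.names = FALSE))
  i <- match(block, object@labels)
  if (is.na(i)) stop(sprintf("no block labeled '%s'", block), call. = FALSE)
  object@times[[i]]
})
#' @rdname accessors
setMethod("nStimuli", "StimulusProtocol", function(object)
  length(unlist(object@times, use.names = FALSE)))

#' @rdname accessors
setMethod("matchedPairs", "MatchResult", function(object) object@pairs)
#' @rdname accessors
setMethod("unmatchedEphys", "MatchResult", function(object) object@unmatchedEphys)
#' @rdname accessors
setMethod("unmatchedOptical", "MatchResult", function(object) object@unmatchedOptical)
#' @rdname accessors
setMethod("matchTolerance", "MatchResult", function(object) object@tolerance)

#' @rdname accessors
setMethod("azAmplitudes", "AZMatrix", function(object) object@amplitudes)
#' @rdname accessors
setMethod("azIds", "AZMatrix", function(object) object@azIds)

setMethod("show", "AcquisitionMeta", function(object) {
  cat(sprintf("AcquisitionMeta: %.6g fps (dt = %.6g ms), start %.6g ms, channels: %s\n",
              object@frameRate, frameInterval(object), object@startTime,
              paste(object@channelNames, collapse = ", ")))
})

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording '%s': %d frames at %.6g fps (%s)%s\n",
              object@roiId, length(object@signal), object@meta@frameRate,
              object@mode,
              if (length(object@reference)) " + reference channel" else ""))
  cat(sprintf("  time span %.6g-%.6g ms; signal range [%.6g, %.6g]\n",
              startTime(object), max(timePoints(object)),
              min(object@signal), max(object@signal)))
})

setMethod("show", "NormalizedTrace", function(object) {
  cat(sprintf("NormalizedTrace '%s' (%s): %d frames at %.6g fps\n",
              object@roiId, toupper(object@mode), length(object@values),
              object@meta@frameRate))
  cat(sprintf("  values range [%.4g, %.4g]; baseline range [%.4g, %.4g]\n",
              min(object@values), max(object@values),
              min(object@baseline), max(object@baseline)))
})

setMethod("show", "StimulusProtocol", function(object) {
  cat(sprintf("StimulusProtocol: %d block(s), %d stimuli\n",
              length(object@labels), nStimuli(object)))
  for (i in seq_along(object@labels)) {
    tt <- object@times[[i]]
    cat(sprintf("  '%s': %d stimuli at %.4g Hz, %.6g-%.6g ms\n",
                object@labels[i], length(tt), object@frequencies[i],
                if (length(tt)) tt[1] else NA, if (length(tt)) tt[length(tt)] else NA))
  }
})

setMethod("show", "MatchResult", function(object) {
  cat(sprintf("MatchResult: %d pairs (tolerance %.4g ms), %d unmatched ephys, %d unmatched optical\n",
              nrow(object@pairs), object@tolerance,
              nrow(object@unmatchedEphys), nrow(object@unmatchedOptical)))
})

setMethod("show", "AZMatrix", function(object) {
  cat(sprintf("AZMatrix: %d active zones x %d stimuli; response range [%.4g, %.4g]\n",
              nrow(object@amplitudes), ncol(object@amplitudes),
              min(object@amplitudes), max(object@amplitudes)))
})
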