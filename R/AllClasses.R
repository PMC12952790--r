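#' @import methods
NULL

#' Acquisition metadata for a fluorescence recording
#'
#' Captures the timebase of an imaging acquisition: the frame rate in frames
#' per second, the millisecond offset of frame 0, and channel labels. The
#' frame interval is derived as \eqn{\Delta t = 1000 / \mathrm{frame\ rate}}
#' milliseconds and is available through [frameInterval()]. Frame indices are
#' 0-based: frame \eqn{k} maps to time \eqn{t_0 + k \Delta t} ms.
#'
#' @slot frameRate frames per second (> 0).
#' @slot startTime ms offset of frame 0.
#' @slot channelNames labels for the signal and (optionally) reference channel.
#'
#' @seealso [acquisitionMeta()], [frameInterval()], [framesToMs()]
#' @export
setClass("AcquisitionMeta",
  representation(frameRate = "numeric", startTime = "numeric",
                 channelNames = "character"),
  prototype(frameRate = NA_real_, startTime = 0, channelNames = "signal"))

setValidity("AcquisitionMeta", function(object) {
  msg <- character()
  if (length(object@frameRate) != 1L || !is.finite(object@frameRate) ||
      object@frameRate <= 0) {
    msg <- c(msg, "frameRate must be a single finite value > 0")
  }
  if (length(object@startTime) != 1L || !is.finite(object@startTime)) {
    msg <- c(msg, "startTime must be a single finite value")
  }
  if (length(object@channelNames) < 1L) {
    msg <- c(msg, "at least one channel name is required")
  }
  if (length(msg)) msg else TRUE
})

#' Construct acquisition metadata
#'
#' @param frameRate frames per second (> 0).
#' @param startTime ms offset of frame 0 (default 0).
#' @param channelNames channel labels; one entry for single-channel data, two
#'   (signal, reference) for ratiometric recordings.
#' @return An [AcquisitionMeta-class] object.
#' @examples
#' m <- acquisitionMeta(frameRate = 100)
#' frameInterval(m)   # 10 ms
#' @export
acquisitionMeta <- function(frameRate, startTime = 0, channelNames = "signal") {
  new("AcquisitionMeta", frameRate = as.numeric(frameRate),
      startTime = as.numeric(startTime), channelNames = channelNames)
}

#' A single-ROI fluorescence recording
#'
#' Holds one region of interest's mean-intensity time series, with optional
#' aligned reference-channel series (a calcium-insensitive fluorophore such as
#' mScarlet used for ratiometric normalization). The `mode` flag records
#' whether the stored values are raw intensities or already-normalized
#' dF/F / dR/R traces.
#'
#' @slot meta an [AcquisitionMeta-class].
#' @slot roiId ROI label (column header of the source table).
#' @slot signal fluorescence intensities, length >= 2, all finite.
#' @slot reference optional reference-channel intensities (length 0 when
#'   absent; otherwise same length as `signal`).
#' @slot mode one of `"raw"`, `"dff"`, `"drr"`.
#'
#' @seealso [readTraceTable()], [normalizeDFF()], [normalizeDRR()]
#' @export
setClass("Recording",
  representation(meta = "AcquisitionMeta", roiId = "character",
                 signal = "numeric", reference = "numeric", mode = "character"),
  prototype(roiId = "roi", reference = numeric(0), mode = "raw"))

setValidity("Recording", function(object) {
  msg <- character()
  if (length(object@signal) < 2L) msg <- c(msg, "signal must have length >= 2")
  if (any(!is.finite(object@signal))) msg <- c(msg, "signal values must be finite")
  if (length(object@reference)) {
    if (length(object@reference) != length(object@signal)) {
      msg <- c(msg, "reference must match signal length")
    }
    if (any(!is.finite(object@reference))) {
      msg <- c(msg, "reference values must be finite")
    }
  }
  if (!object@mode %in% c("raw", "dff", "drr")) {
    msg <- c(msg, "mode must be one of 'raw', 'dff', 'drr'")
  }
  if (length(object@roiId) != 1L) msg <- c(msg, "roiId must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a Recording
#'
#' @param signal numeric intensity series (length >= 2, finite).
#' @param meta an [AcquisitionMeta-class] or a frame rate in fps (coerced).
#' @param roiId ROI label.
#' @param reference optional reference-channel series of identical length.
#' @param mode `"raw"` (default), `"dff"` or `"drr"` for pre-normalized input.
#' @return A [Recording-class] object.
#' @examples
#' rec <- recording(100 + sin(seq(0, 6, length.out = 50)), meta = 100)
#' timePoints(rec)[1:3]
#' @export
recording <- function(signal, meta, roiId = "roi", reference = numeric(0),
                      mode = "raw") {
  if (!is(meta, "AcquisitionMeta")) meta <- acquisitionMeta(frameRate = meta)
  new("Recording", meta = meta, roiId = as.character(roiId),
      signal = as.numeric(signal), reference = as.numeric(reference),
      mode = mode)
}

#' A normalized (dF/F or dR/R) trace with its baseline
#'
#' The result of baseline normalization: per-frame fractional changes together
#' with the time-varying baseline that produced them and the raw series they
#' were derived from, so that `values == (raw - baseline) / baseline` holds by
#' construction and the raw trace can be recovered exactly.
#'
#' @slot meta an [AcquisitionMeta-class].
#' @slot roiId ROI label.
#' @slot values dF/F or dR/R per frame (dimensionless).
#' @slot baseline F0(t) or R0(t) per frame, strictly positive.
#' @slot raw the raw series (F or R) the normalization was applied to.
#' @slot mode `"dff"` or `"drr"`.
#' @slot params named list recording the baseline parameters used
#'   (window, method, percentile/fraction, smoothing window).
#'
#' @export
setClass("NormalizedTrace",
  representation(meta = "AcquisitionMeta", roiId = "character",
                 values = "numeric", baseline = "numeric", raw = "numeric",
                 mode = "character", params = "list"),
  prototype(roiId = "roi", mode = "dff", params = list()))

setValidity("NormalizedTrace", function(object) {
  msg <- character()
  n <- length(object@values)
  if (n < 2L) msg <- c(msg, "values must have length >= 2")
  if (length(object@baseline) != n) msg <- c(msg, "baseline length must match values")
  if (length(object@raw) != n) msg <- c(msg, "raw length must match values")
  if (any(!is.finite(object@values))) msg <- c(msg, "values must be finite")
  if (any(!is.finite(object@baseline)) || any(object@baseline <= 0)) {
    msg <- c(msg, "baseline must be finite and strictly positive")
  }
  if (!object@mode %in% c("dff", "drr")) msg <- c(msg, "mode must be 'dff' or 'drr'")
  if (n >= 2L && any(abs(object@values - (object@raw - object@baseline) /
                           object@baseline) > 1e-9 + 1e-9 * abs(object@values))) {
    msg <- c(msg, "values must equal (raw - baseline)/baseline")
  }
  if (length(msg)) msg else TRUE
})

#' A stimulation protocol of frequency blocks
#'
#' Ordered stimulus times grouped into labeled frequency blocks, e.g. 10
#' action potentials at 1 Hz followed by a 17-stimulus train at 21.3 Hz.
#' Stimulus times are strictly increasing within and across blocks, and
#' within a block the inter-stimulus interval matches 1000/frequency.
#'
#' @slot labels block labels, one per block.
#' @slot frequencies block stimulation frequencies (Hz).
#' @slot times list of numeric vectors of stimulus times (ms), one per block.
#' @slot pulseDuration stimulus pulse width in ms (metadata only).
#'
#' @seealso [stimulusProtocol()], [protocolFromBlocks()]
#' @export
setClass("StimulusProtocol",
  representation(labels = "character", frequencies = "numeric",
                 times = "list", pulseDuration = "numeric"),
  prototype(pulseDuration = NA_real_))

setValidity("StimulusProtocol", function(object) {
  msg <- character()
  nb <- length(object@labels)
  if (length(object@frequencies) != nb || length(object@times) != nb) {
    msg <- c(msg, "labels, frequencies and times must have one entry per block")
  }
  if (anyDuplicated(object@labels)) msg <- c(msg, "block labels must be unique")
  all_t <- unlist(object@times, use.names = FALSE)
  if (length(all_t) && any(diff(all_t) <= 0)) {
    msg <- c(msg, "stimulus times must be strictly increasing within and across blocks")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a stimulation protocol from explicit stimulus times
#'
#' @param labels character vector of block labels.
#' @param frequencies numeric vector of block frequencies (Hz).
#' @param times list of numeric stimulus-time vectors (ms), one per block.
#' @param pulseDuration optional pulse width (ms, metadata only).
#' @param isiTolerance allowed relative deviation of within-block
#'   inter-stimulus intervals from 1000/frequency (default 5%, accommodating
#'   stimulus times quantized to the imaging frame clock).
#' @return A [StimulusProtocol-class].
#' @examples
#' p <- protocolFromBlocks(label = "train", frequencyHz = 21.3,
#'                         nStimuli = 17, firstStimulusMs = 1000)
#' nStimuli(p)
#' @export
stimulusProtocol <- function(labels, frequencies, times, pulseDuration = NA_real_,
                             isiTolerance = 0.05) {
  times <- lapply(times, as.numeric)
  for (i in seq_along(times)) {
    tt <- times[[i]]
    if (length(tt) >= 2L) {
      isi <- diff(tt)
      expect <- 1000 / frequencies[i]
      if (any(abs(isi - expect) > isiTolerance * expect)) {
        stop(sprintf("block '%s': inter-stimulus intervals deviate from 1000/%g ms",
                     labels[i], frequencies[i]), call. = FALSE)
      }
    }
  }
  new("StimulusProtocol", labels = as.character(labels),
      frequencies = as.numeric(frequencies), times = times,
      pulseDuration = as.numeric(pulseDuration))
}

#' Construct a protocol from block descriptions
#'
#' Convenience constructor generating exact stimulus times for blocks given as
#' (label, frequency, count, onset of first stimulus).
#'
#' @param label,frequencyHz,nStimuli,firstStimulusMs vectors of equal length,
#'   one entry per block.
#' @param pulseDuration optional pulse width (ms).
#' @return A [StimulusProtocol-class].
#' @export
protocolFromBlocks <- function(label, frequencyHz, nStimuli, firstStimulusMs,
                               pulseDuration = NA_real_) {
  stopifnot(length(label) == length(frequencyHz),
            length(label) == length(nStimuli),
            length(label) == length(firstStimulusMs))
  times <- mapply(function(f, n, t0) t0 + (seq_len(n) - 1) * 1000 / f,
                  frequencyHz, nStimuli, firstStimulusMs, SIMPLIFY = FALSE)
  stimulusProtocol(label, frequencyHz, times, pulseDuration)
}

#' Paired optical-electrophysiology events
#'
#' Result of greedy nearest-in-time one-to-one matching between optical
#' transients and electrophysiological miniature events within a temporal
#' tolerance. Counts are conserved: every input event appears exactly once,
#' either in `pairs` or in one of the unmatched tables.
#'
#' @slot pairs data.frame with columns `ephys_time`, `ephys_amplitude`,
#'   `optical_time`, `optical_amplitude`, `dt` (|optical - ephys| ms).
#' @slot unmatchedEphys data.frame (`time`, `amplitude`) of unmatched
#'   electrophysiological events.
#' @slot unmatchedOptical data.frame (`time`, `amplitude`) of unmatched
#'   optical events.
#' @slot tolerance matching tolerance in ms.
#'
#' @seealso [matchEvents()], [detectionFraction()], [amplitudeCorrelation()]
#' @export
setClass("MatchResult",
  representation(pairs = "data.frame", unmatchedEphys = "data.frame",
                 unmatchedOptical = "data.frame", tolerance = "numeric"))

setValidity("MatchResult", function(object) {
  msg <- character()
  need <- c("ephys_time", "ephys_amplitude", "optical_time",
            "optical_amplitude", "dt")
  if (!all(need %in% names(object@pairs))) {
    msg <- c(msg, "pairs must have ephys/optical time+amplitude and dt columns")
  } else if (nrow(object@pairs) &&
             any(object@pairs$dt > object@tolerance + 1e-9)) {
    msg <- c(msg, "all pair |dt| must be <= tolerance")
  }
  if (length(object@tolerance) != 1L || object@tolerance < 0) {
    msg <- c(msg, "tolerance must be a single value >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Active-zone by stimulus response matrix
#'
#' Peak responses (dF/F or dR/R) of each active zone (AZ) to each stimulus in
#' a trial series: rows are AZs, columns stimuli, so row `i` column `j` is AZ
#' `i`'s peak response to stimulus `j`. Inputs to the AZ statistics layer
#' ([azPairwiseTests()], [iqrFlags()]).
#'
#' @slot amplitudes numeric matrix, AZ x stimulus, all finite.
#' @slot azIds AZ labels (rownames of `amplitudes`).
#'
#' @export
setClass("AZMatrix",
  representation(amplitudes = "matrix", azIds = "character"))

setValidity("AZMatrix", function(object) {
  msg <- character()
  if (!is.numeric(object@amplitudes)) msg <- c(msg, "amplitudes must be numeric")
  else if (any(!is.finite(object@amplitudes))) msg <- c(msg, "amplitudes must be finite")
  if (length(object@azIds) != nrow(object@amplitudes)) {
    msg <- c(msg, "azIds must have one entry per row")
  }
  if (length(msg)) msg else TRUE
}
)

#' Construct an AZMatrix
#'
#' @param amplitudes numeric matrix (AZ x stimulus) of peak responses.
#' @param azIds optional AZ labels (defaults to rownames or AZ1..AZn).
#' @return An [AZMatrix-class].
#' @export
azMatrix <- function(amplitudes, azIds = NULL) {
  amplitudes <- as.matrix(amplitudes)
  if (is.null(azIds)) {
    azIds <- rownames(amplitudes)
    if (is.null(azIds)) azIds <- paste0("AZ", seq_len(nrow(amplitudes)))
  }
  rownames(amplitudes) <- azIds
  new("AZMatrix", amplitudes = amplitudes, azIds = as.character(azIds))
}
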