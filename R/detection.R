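#' @include AllClasses.R io.R
NULL

#' Peak-detection settings
#'
#' The three tunable detection criteria plus the manual-selection search
#' radius. A candidate peak must (1) reach `threshold` in normalized units,
#' (2) keep the trace above half its own height for at least `minWidth`
#' contiguous frames around the peak, and (3) lie at least `minDistance` ms
#' from any larger accepted peak.
#'
#' @param threshold minimum peak value (dF/F or dR/R units).
#' @param minWidth minimum width at half height, in frames (>= 1).
#' @param minDistance minimum inter-peak separation in ms (>= 0); among peaks
#'   closer than this, the larger is kept (ties go to the earlier one).
#' @param searchRadius ms window for manual nearest-peak selection
#'   (default 200).
#' @param smoothWindow optional centered moving-average window (frames)
#'   applied to the trace before candidate detection (default 1 = none).
#'   Smoothing raises the effective signal-to-noise ratio for
#'   near-threshold minis; amplitudes of detected events are measured on the
#'   smoothed series so the reported values describe the detected waveform.
#' @return A validated list of class `"DetectionSettings"`.
#' @export
detectionSettings <- function(threshold, minWidth = 1L, minDistance = 0,
                              searchRadius = 200, smoothWindow = 1L) {
  assertScalarNumber(threshold, "threshold")
  if (!is.numeric(minWidth) || minWidth < 1) stop("minWidth must be >= 1", call. = FALSE)
  if (!is.numeric(minDistance) || minDistance < 0) {
    stop("minDistance must be >= 0", call. = FALSE)
  }
  assertScalarNumber(searchRadius, "searchRadius", positive = TRUE)
  if (!is.numeric(smoothWindow) || smoothWindow < 1) {
    stop("smoothWindow must be >= 1", call. = FALSE)
  }
  structure(list(threshold = threshold, minWidth = as.integer(minWidth),
                 minDistance = minDistance, searchRadius = searchRadius,
                 smoothWindow = as.integer(smoothWindow)),
            class = "DetectionSettings")
}

# 1-based indices of local maxima: strictly greater than the nearest distinct
# neighbors on both sides; a plateau resolves to its first frame. Trace ends
# are never peaks.
localMaxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  mid <- 2:(k - 1L)
  isPeak <- r$values[mid] > r$values[mid - 1L] & r$values[mid] > r$values[mid + 1L]
  starts[mid][isPeak]
}

# Contiguous frames around peak index i with v >= half the peak height.
halfHeightWidth <- function(v, i) {
  half <- v[i] / 2
  lo <- i
  while (lo > 1L && v[lo - 1L] >= half) lo <- lo - 1L
  hi <- i
  n <- length(v)
  while (hi < n && v[hi + 1L] >= half) hi <- hi + 1L
  hi - lo + 1L
}

#' Automated transient detection
#'
#' Finds candidate peaks as local maxima of the normalized trace, applies the
#' three detection criteria of [detectionSettings()], and returns one event
#' row per accepted peak (in time order, `source = "auto"`, kinetics
#' unfitted). Minimum-distance suppression keeps the larger of any two peaks
#' closer than `minDistance` ms, breaking ties toward the earlier peak.
#'
#' @param trace a [NormalizedTrace-class].
#' @param settings a [detectionSettings()] object.
#' @param amplitudeMode amplitude convention passed to [measureAmplitude()].
#' @return An event data.frame (see [emptyEvents()] for the column contract;
#'   `peak_index` is the 0-based frame number).
#' @export
detectPeaks <- function(trace, settings,
                        amplitudeMode = c("from_zero", "from_local_base")) {
  amplitudeMode <- match.arg(amplitudeMode)
  stopifnot(is(trace, "NormalizedTrace"), inherits(settings, "DetectionSettings"))
  v <- traceValues(trace)
  if (settings$smoothWindow > 1L) v <- smoothReference(v, settings$smoothWindow)
  tp <- timePoints(trace)
  cand <- localMaxima(v)
  cand <- cand[v[cand] >= settings$threshold]
  if (settings$minWidth > 1L) {
    wOk <- vapply(cand, function(i) halfHeightWidth(v, i) >= settings$minWidth,
                  logical(1))
    cand <- cand[wOk]
  }
  if (length(cand) > 1L && settings$minDistance > 0) {
    # Greedy by amplitude (ties -> earlier): accept unless within minDistance
    # of an already-accepted, larger-or-equal peak.
    ord <- order(-v[cand], tp[cand])
    keep <- logical(length(cand))
    accTimes <- numeric(0)
    for (j in ord) {
      if (!length(accTimes) || all(abs(tp[cand[j]] - accTimes) >= settings$minDistance)) {
        keep[j] <- TRUE
        accTimes <- c(accTimes, tp[cand[j]])
      }
    }
    cand <- sort(cand[keep])
  }
  amp <- vapply(cand, function(i) {
    if (amplitudeMode == "from_zero") return(v[i])
    span <- max(settings$minDistance, frameInterval(trace))
    inWin <- tp >= tp[i] - span & tp < tp[i]
    v[i] - if (any(inWin)) min(v[inWin]) else 0
  }, numeric(1))
  makeEvents(roiId(trace), cand - 1L, tp[cand], amp, source = "auto")
}

#' Manual nearest-peak selection
#'
#' Returns the local maximum nearest in time to a user-indicated position,
#' ignoring the amplitude threshold — the operation exists to rescue events
#' the automatic pass missed. Exact ties in distance resolve to the earlier
#' peak.
#'
#' @param trace a [NormalizedTrace-class].
#' @param tClick indicated time (ms), within the trace's span.
#' @param settings a [detectionSettings()]; only `searchRadius` is used.
#' @param amplitudeMode amplitude convention for the returned event.
#' @return A one-row event data.frame with `source = "manual"`.
#' @export
nearestPeak <- function(trace, tClick, settings,
                        amplitudeMode = c("from_zero", "from_local_base")) {
  amplitudeMode <- match.arg(amplitudeMode)
  stopifnot(is(trace, "NormalizedTrace"))
  tp <- timePoints(trace)
  if (tClick < tp[1L] || tClick > tp[length(tp)]) {
    stop("tClick lies outside the trace's time span", call. = FALSE)
  }
  v <- traceValues(trace)
  cand <- localMaxima(v)
  if (length(cand)) {
    d <- abs(tp[cand] - tClick)
    cand <- cand[d <= settings$searchRadius]
    d <- d[d <= settings$searchRadius]
  }
  if (!length(cand)) {
    stop(sprintf("no local maximum within %.6g ms of t = %.6g ms",
                 settings$searchRadius, tClick), call. = FALSE)
  }
  best <- cand[order(d, tp[cand])][1L]
  amp <- measureAmplitude(trace, best - 1L, mode = amplitudeMode,
                          spanMs = max(settings$minDistance, frameInterval(trace)))
  makeEvents(roiId(trace), best - 1L, tp[best], amp, source = "manual")
}

#' Measure an event's amplitude
#'
#' `from_zero` (default) reads the normalized trace value at the peak — the
#' baseline of a normalized trace is zero by construction. `from_local_base`
#' subtracts the minimum of the trace over the `spanMs` window preceding the
#' peak, which discounts the pedestal left by an unresolved earlier event.
#'
#' @param trace a [NormalizedTrace-class].
#' @param peakFrame 0-based frame number of the peak (as in the event table).
#' @param mode `"from_zero"` or `"from_local_base"`.
#' @param spanMs lookback span (ms) for the local base (default 200).
#' @return The amplitude in dF/F or dR/R units.
#' @export
measureAmplitude <- function(trace, peakFrame,
                             mode = c("from_zero", "from_local_base"),
                             spanMs = 200) {
  mode <- match.arg(mode)
  v <- traceValues(trace)
  i <- as.integer(peakFrame) + 1L
  if (i < 1L || i > length(v)) stop("peakFrame out of bounds", call. = FALSE)
  if (mode == "from_zero") return(v[i])
  tp <- timePoints(trace)
  inWin <- tp >= tp[i] - spanMs & tp < tp[i]
  base <- if (any(inWin)) min(v[inWin]) else 0
  v[i] - base
}
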