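#' @include AllClasses.R kinetics.R
NULL

#' Assign detected events to stimulation blocks
#'
#' Labels each event with the block of the nearest preceding stimulus when
#' the latency (peak time minus stimulus time) lies in `(0, latencyWindow]`
#' ms; events outside every latency window are labeled `"unassigned"`. Each
#' stimulus claims at most one event — the one nearest in latency — and any
#' surplus events near the same stimulus stay unassigned. Relabeling is
#' idempotent.
#'
#' @param events a time-sorted event data.frame.
#' @param protocol a [StimulusProtocol-class].
#' @param latencyWindow maximum stimulus-to-peak latency (ms, default 100).
#' @return The event data.frame with the `label` column filled.
#' @export
partitionEvents <- function(events, protocol, latencyWindow = 100) {
  stopifnot(is(protocol, "StimulusProtocol"))
  if (!nrow(events)) return(events)
  if (is.unsorted(events$peak_time)) {
    stop("events must be sorted by peak_time", call. = FALSE)
  }
  labels <- rep("unassigned", nrow(events))
  stim <- stimulusTimes(protocol)
  if (length(stim)) {
    blockOf <- rep(blockLabels(protocol),
                   vapply(blockLabels(protocol),
                          function(b) length(stimulusTimes(protocol, b)),
                          integer(1)))
    # nearest preceding stimulus per event
    prec <- findInterval(events$peak_time, stim + 1e-12)
    lat <- events$peak_time - ifelse(prec >= 1L, stim[pmax(prec, 1L)], Inf)
    ok <- prec >= 1L & lat > 0 & lat <= latencyWindow
    # one event per stimulus: nearest latency wins
    for (s in unique(prec[ok])) {
      rows <- which(ok & prec == s)
      best <- rows[order(lat[rows], events$peak_time[rows])][1L]
      labels[best] <- blockOf[s]
    }
  }
  events$label <- labels
  events
}

#' Summarize a stimulus-train response
#'
#' Computes the train metrics reported for high-frequency stimulation:
#' amplitudes of the first and final transients measured from the pre-train
#' baseline (the mean trace value over `baselineWindow` ms before the first
#' stimulus), the facilitation index (final/first), and the post-train decay
#' constant from a single-exponential fit over `postTrainFitMs` following the
#' final peak. First/final peaks are located as the trace maximum within one
#' inter-stimulus interval after the first/last stimulus (`peakWindowMs`
#' overrides).
#'
#' @param trace a [NormalizedTrace-class] containing the train.
#' @param protocol a [StimulusProtocol-class].
#' @param block label of the train block (default: last block).
#' @param baselineWindow pre-train baseline window (ms, default 100).
#' @param peakWindowMs search window after each stimulus for its peak
#'   (default: the block's inter-stimulus interval).
#' @param postTrainFitMs decay-fit span after the final peak (ms, default
#'   1000).
#' @return A list: `first_amplitude`, `final_amplitude`,
#'   `facilitation_index`, `post_train_tau` (ms, NA if the decay fit fails),
#'   `baseline`, `n_stimuli`.
#' @export
trainSummary <- function(trace, protocol, block = NULL, baselineWindow = 100,
                         peakWindowMs = NULL, postTrainFitMs = 1000) {
  stopifnot(is(trace, "NormalizedTrace"), is(protocol, "StimulusProtocol"))
  if (is.null(block)) block <- tail(blockLabels(protocol), 1L)
  stim <- stimulusTimes(protocol, block)
  if (length(stim) < 2L) stop("train block needs >= 2 stimuli", call. = FALSE)
  isi <- 1000 / blockFrequencies(protocol)[[block]]
  if (is.null(peakWindowMs)) peakWindowMs <- isi
  tp <- timePoints(trace)
  v <- traceValues(trace)

  inBase <- tp >= stim[1L] - baselineWindow & tp < stim[1L]
  if (!any(inBase)) stop("empty pre-train baseline window", call. = FALSE)
  base <- mean(v[inBase])

  peakAfter <- function(t0, which) {
    inWin <- tp > t0 & tp <= t0 + peakWindowMs
    if (!any(inWin)) {
      stop(sprintf("no frames after the %s stimulus", which), call. = FALSE)
    }
    iRel <- which.max(v[inWin])
    i <- which(inWin)[iRel]
    if (v[i] <= base) {
      stop(sprintf("no detectable peak after the %s stimulus", which),
           call. = FALSE)
    }
    i
  }
  iFirst <- peakAfter(stim[1L], "first")
  iLast <- peakAfter(stim[length(stim)], "final")
  firstAmp <- v[iFirst] - base
  finalAmp <- v[iLast] - base

  tau <- NA_real_
  dec <- tryCatch(fitDecay(trace, iLast - 1L, fitSpanMs = postTrainFitMs),
                  error = function(e) NULL)
  if (!is.null(dec) && isTRUE(dec$converged)) tau <- dec$tau

  list(first_amplitude = firstAmp, final_amplitude = finalAmp,
       facilitation_index = finalAmp / firstAmp, post_train_tau = tau,
       baseline = base, n_stimuli = length(stim))
}
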