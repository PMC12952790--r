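#' @include AllClasses.R
NULL

#' Specification for a synthetic recording
#'
#' Parameters of the synthetic fluorescence generator. Transients are built
#' from a unit-peak kernel that rises as a saturating exponential up to its
#' peak and decays as a pure exponential afterwards, so a recovered event of
#' true amplitude A peaks at dF/F = A on a noiseless flat baseline and the
#' kernel's two time constants are exactly what the rise/decay fits
#' estimate. Slow
#' photobleaching is multiplicative-exponential: `bleach` is the factor the
#' baseline has decayed to by the end of the recording (0.97 emulates the
#' typical 2-5% loss over a 60 s widefield acquisition; 1 = none). Noise is
#' additive Gaussian in intensity units.
#'
#' @param durationMs recording length (ms).
#' @param frameRate frames per second.
#' @param baselineF resting fluorescence intensity.
#' @param amplitude event peak amplitude in dF/F units.
#' @param tauRise,tauDecay kernel time constants (ms).
#' @param miniRate spontaneous (Poisson) event rate in events/s.
#' @param noiseSigma additive Gaussian noise SD, intensity units.
#' @param bleach end-of-recording bleaching factor in (0, 1.5].
#' @param bleachShape `"exponential"` (default) or `"linear"` baseline decay
#'   toward `bleach`; the linear option exercises the linear bleach-trend
#'   correction.
#' @param reference optional list for a dual-channel recording:
#'   `baselineF`, `noiseSigma`, `bleach` for the calcium-insensitive
#'   reference channel (which carries no events).
#' @param seed integer seed; identical specs with identical seeds generate
#'   bit-identical recordings.
#' @return A validated list of class `"SimSpec"`.
#' @export
simSpec <- function(durationMs = 60000, frameRate = 100, baselineF = 100,
                    amplitude = 0.5, tauRise = 14, tauDecay = 67,
                    miniRate = 0.5, noiseSigma = 1, bleach = 1,
                    bleachShape = c("exponential", "linear"),
                    reference = NULL, seed = 1L) {
  bleachShape <- match.arg(bleachShape)
  assertScalarNumber(durationMs, "durationMs", positive = TRUE)
  assertScalarNumber(frameRate, "frameRate", positive = TRUE)
  assertScalarNumber(baselineF, "baselineF", positive = TRUE)
  assertScalarNumber(tauRise, "tauRise", positive = TRUE)
  assertScalarNumber(tauDecay, "tauDecay", positive = TRUE)
  if (!is.numeric(miniRate) || miniRate < 0) stop("miniRate must be >= 0", call. = FALSE)
  if (!is.numeric(noiseSigma) || noiseSigma < 0) {
    stop("noiseSigma must be >= 0", call. = FALSE)
  }
  if (!is.numeric(bleach) || bleach <= 0 || bleach > 1.5) {
    stop("bleach must lie in (0, 1.5]", call. = FALSE)
  }
  if (!is.null(reference)) {
    if (is.null(reference$baselineF) || reference$baselineF <= 0) {
      stop("reference$baselineF must be > 0", call. = FALSE)
    }
    if (is.null(reference$noiseSigma)) reference$noiseSigma <- 0
    if (is.null(reference$bleach)) reference$bleach <- 1
  }
  structure(list(durationMs = durationMs, frameRate = frameRate,
                 baselineF = baselineF, amplitude = amplitude,
                 tauRise = tauRise, tauDecay = tauDecay, miniRate = miniRate,
                 noiseSigma = noiseSigma, bleach = bleach,
                 bleachShape = bleachShape, reference = reference,
                 seed = as.integer(seed)),
            class = "SimSpec")
}

# Unit-peak transient kernel: saturating exponential rise up to the peak time
# t* = tr * log(1 + td/tr), pure exponential decay afterwards. The rise phase
# is exactly A(1 - e^(-t/tr)) and the decay phase exactly e^(-(t-t*)/td), so
# the kernel's time constants are precisely the quantities the rise/decay
# fitting conventions estimate.
transientKernel <- function(t, tauRise, tauDecay) {
  tStar <- tauRise * log(1 + tauDecay / tauRise)
  riseSat <- 1 - exp(-tStar / tauRise)
  out <- numeric(length(t))
  up <- t >= 0 & t <= tStar
  dn <- t > tStar
  out[up] <- (1 - exp(-t[up] / tauRise)) / riseSat
  out[dn] <- exp(-(t[dn] - tStar) / tauDecay)
  out
}

#' Peak lag of the synthetic transient kernel
#'
#' Time from event onset to the kernel's peak,
#' \eqn{t^* = \tau_r \log(1 + \tau_d/\tau_r)} ms. Useful for aligning
#' detected peak times with ground-truth event onset times.
#'
#' @param tauRise,tauDecay kernel time constants (ms).
#' @return Peak lag in ms.
#' @export
kernelPeakLag <- function(tauRise, tauDecay) {
  tauRise * log(1 + tauDecay / tauRise)
}

bleachCurve <- function(tp, durationMs, bleach, shape) {
  if (bleach == 1) return(rep(1, length(tp)))
  if (shape == "exponential") bleach^(tp / durationMs)
  else 1 + (bleach - 1) * tp / durationMs
}

# Shared core: deterministic event times + per-event amplitudes -> Recording.
buildRecording <- function(spec, eventTimes, eventAmps, roiId) {
  n <- floor(spec$durationMs * spec$frameRate / 1000)
  meta <- acquisitionMeta(frameRate = spec$frameRate, startTime = 0)
  tp <- (seq_len(n) - 1L) * 1000 / spec$frameRate
  clean <- rep(spec$baselineF, n)
  for (k in seq_along(eventTimes)) {
    clean <- clean + spec$baselineF * eventAmps[k] *
      transientKernel(tp - eventTimes[k], spec$tauRise, spec$tauDecay)
  }
  sig <- clean * bleachCurve(tp, spec$durationMs, spec$bleach, spec$bleachShape)
  if (spec$noiseSigma > 0) sig <- sig + rnorm(n, 0, spec$noiseSigma)
  ref <- numeric(0)
  if (!is.null(spec$reference)) {
    r <- spec$reference
    ref <- r$baselineF *
      bleachCurve(tp, spec$durationMs, r$bleach, spec$bleachShape)
    if (r$noiseSigma > 0) ref <- ref + rnorm(n, 0, r$noiseSigma)
  }
  recording(sig, meta = meta, roiId = roiId, reference = ref, mode = "raw")
}

#' Simulate a spontaneous (quantal) recording with ground truth
#'
#' Event times follow a homogeneous Poisson process at `miniRate` events/s;
#' each event adds a unit-peak rise-decay kernel scaled to
#' `baselineF * amplitude`. The trace is
#' `(baseline + events) * bleach_curve + noise`. The ground-truth table lists
#' each event's time and true dF/F amplitude.
#'
#' @param spec a [simSpec()] object.
#' @param roiId label for the generated Recording.
#' @return A list: `recording` ([Recording-class]) and `truth` (data.frame
#'   `time`, `amplitude`).
#' @export
simulateQuantalRecording <- function(spec, roiId = "sim") {
  stopifnot(inherits(spec, "SimSpec"))
  withSeed(spec$seed, {
    nEv <- rpois(1L, spec$miniRate * spec$durationMs / 1000)
    times <- sort(runif(nEv, 0, spec$durationMs))
    rec <- buildRecording(spec, times, rep(spec$amplitude, nEv), roiId)
    list(recording = rec,
         truth = data.frame(time = times,
                            amplitude = rep(spec$amplitude, nEv)))
  })
}

#' Simulate an evoked recording under a stimulation protocol
#'
#' Places one deterministic transient at every stimulus time, scaled by a
#' per-stimulus gain (linear superposition), optionally with a
#' calcium-insensitive reference channel carrying its own bleaching and noise
#' but no events.
#'
#' @param spec a [simSpec()] object (set `spec$reference` for dual-channel).
#' @param protocol a [StimulusProtocol-class].
#' @param gains numeric vector of per-stimulus amplitude multipliers, one per
#'   stimulus across all blocks.
#' @param roiId label for the generated Recording.
#' @return A list: `recording` and `truth` (`time`, `amplitude`, `gain`,
#'   `block`).
#' @export
simulateEvokedRecording <- function(spec, protocol, gains, roiId = "sim") {
  stopifnot(inherits(spec, "SimSpec"), is(protocol, "StimulusProtocol"))
  stim <- stimulusTimes(protocol)
  if (length(gains) != length(stim)) {
    stop(sprintf("gains has length %d but the protocol has %d stimuli",
                 length(gains), length(stim)), call. = FALSE)
  }
  blockOf <- rep(blockLabels(protocol),
                 vapply(blockLabels(protocol),
                        function(b) length(stimulusTimes(protocol, b)),
                        integer(1)))
  withSeed(spec$seed, {
    rec <- buildRecording(spec, stim, spec$amplitude * gains, roiId)
    list(recording = rec,
         truth = data.frame(time = stim, amplitude = spec$amplitude * gains,
                            gain = gains, block = blockOf))
  })
}

#' Simulate paired optical-electrophysiology miniature events
#'
#' Draws `n` miniature events with amplitude pairs from a bivariate
#' lognormal; the optical twin of each ephys event shares its time up to a
#' uniform jitter of at most `jitterMs`, and a `dropout` fraction of optical
#' events is deleted independently (emulating minis below the optical
#' detection limit). `rho` specifies the Pearson correlation of the
#' amplitude pairs themselves: internally the log-scale correlation is set
#' to \eqn{\log(1 + \rho(e^{\sigma^2} - 1))/\sigma^2}, which the lognormal
#' margins attenuate back to exactly `rho` on the linear scale.
#'
#' @param n number of ephys events.
#' @param rho target Pearson correlation of the amplitude pairs in \[-1, 1\].
#' @param dropout probability in \[0, 1) that an optical event is missing.
#' @param seed integer seed.
#' @param jitterMs maximum |optical - ephys| time offset (ms, default 10).
#' @param meanLogEphys,sdLog lognormal location (log mV; default log(0.6))
#'   and scale of both margins.
#' @param spacingMs nominal inter-event spacing (ms, default 500); events are
#'   laid out on this grid with at most a quarter-spacing uniform offset, so
#'   consecutive events stay at least `spacingMs/2` apart and the temporal
#'   jitter can never make the optical-ephys correspondence ambiguous.
#' @return A list of data.frames `optical` (`time`, `amplitude` in dF/F) and
#'   `ephys` (`time`, `amplitude` in mV), both time-sorted.
#' @export
simulateMatchedPairs <- function(n, rho, dropout = 0, seed = 1L, jitterMs = 10,
                                 meanLogEphys = log(0.6), sdLog = 0.4,
                                 spacingMs = 500) {
  if (!is.numeric(rho) || abs(rho) > 1) stop("rho must lie in [-1, 1]", call. = FALSE)
  if (!is.numeric(dropout) || dropout < 0 || dropout >= 1) {
    stop("dropout must lie in [0, 1)", call. = FALSE)
  }
  withSeed(seed, {
    times <- seq_len(n) * spacingMs + runif(n, -spacingMs / 4, spacingMs / 4)
    # log-scale correlation whose lognormal attenuation yields Pearson rho
    g <- exp(sdLog^2) - 1
    rhoLog <- if (1 + rho * g > 0) log(1 + rho * g) / sdLog^2 else -1
    rhoLog <- max(-1, min(1, rhoLog))
    z1 <- rnorm(n)
    z2 <- rhoLog * z1 + sqrt(1 - rhoLog^2) * rnorm(n)
    ephAmp <- exp(meanLogEphys + sdLog * z1)
    optAmp <- exp(log(0.3) + sdLog * z2)    # optical minis around dF/F 0.3
    jitter <- runif(n, -jitterMs, jitterMs)
    keep <- runif(n) >= dropout
    optical <- data.frame(time = times[keep] + jitter[keep],
                          amplitude = optAmp[keep])
    optical <- optical[order(optical$time), , drop = FALSE]
    rownames(optical) <- NULL
    list(optical = optical,
         ephys = data.frame(time = times, amplitude = ephAmp))
  })
}

#' Simulate an active-zone response matrix
#'
#' Entries are `azMeans[i] + N(0, sigma)` noise, row i holding AZ i's
#' per-stimulus peak responses. The default design (30 AZs, 15 stimuli)
#' mirrors the standard per-genotype AZ-variability experiment.
#'
#' @param nAz number of active zones (default 30).
#' @param nStimuli stimuli per AZ (default 15).
#' @param azMeans per-AZ mean responses (length `nAz`).
#' @param sigma response noise SD.
#' @param seed integer seed.
#' @return An [AZMatrix-class].
#' @export
simulateAZMatrix <- function(nAz = 30, nStimuli = 15,
                             azMeans = rep(0.3, nAz), sigma = 0.05, seed = 1L) {
  if (length(azMeans) != nAz) {
    stop(sprintf("azMeans has length %d but nAz is %d", length(azMeans), nAz),
         call. = FALSE)
  }
  withSeed(seed, {
    m <- matrix(rep(azMeans, nStimuli), nrow = nAz) +
      matrix(rnorm(nAz * nStimuli, 0, sigma), nrow = nAz)
    azMatrix(m)
  })
}

#' Write a simulated recording and its ground truth to disk
#'
#' Writes the recording in the shared ROI-table CSV layout (plus a reference
#' table for dual-channel recordings) and the ground-truth event list as a
#' JSON sidecar.
#'
#' @param sim output of [simulateQuantalRecording()] or
#'   [simulateEvokedRecording()].
#' @param prefix output path prefix; writes `<prefix>_signal.csv`,
#'   optionally `<prefix>_reference.csv`, and `<prefix>_truth.json`.
#' @return Named character vector of written paths, invisibly.
#' @export
writeSimulation <- function(sim, prefix) {
  rec <- sim$recording
  recs <- setNames(list(rec), roiId(rec))
  paths <- c(signal = paste0(prefix, "_signal.csv"))
  writeTraceTable(recs, paths[["signal"]])
  if (hasReference(rec)) {
    paths[["reference"]] <- paste0(prefix, "_reference.csv")
    writeTraceTable(recs, paths[["reference"]], channel = "reference")
  }
  paths[["truth"]] <- paste0(prefix, "_truth.json")
  jsonlite::write_json(sim$truth, paths[["truth"]], digits = NA)
  invisible(paths)
}
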