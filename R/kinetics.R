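#' @include AllClasses.R detection.R
NULL

# Wrap minpack.lm::nls.lm (Levenberg-Marquardt) with the package's convergence
# contract: bounded iterations, relative-change tolerance, convergence flag.
lmFit <- function(par, residFn, lower = NULL, upper = NULL,
                  maxit = 200L, ptol = 1e-8) {
  ctrl <- minpack.lm::nls.lm.control(maxiter = maxit, ptol = ptol, ftol = ptol)
  fit <- minpack.lm::nls.lm(par = par, fn = residFn, lower = lower,
                            upper = upper, control = ctrl)
  list(par = fit$par, rss = sum(fit$fvec^2),
       converged = fit$info %in% 1:4, info = fit$info)
}

fitResult <- function(tau = NA_real_, amplitude = NA_real_, t0 = NA_real_,
                      rss = NA_real_, nPoints = NA_integer_,
                      converged = FALSE, note = NA_character_) {
  list(tau = tau, amplitude = amplitude, t0 = t0, rss = rss,
       nPoints = as.integer(nPoints), converged = converged, note = note)
}

#' Fit the exponential decay of a transient
#'
#' Fits \eqn{y(t) = y_{peak} e^{-t/\tau_{decay}}} to the trace from the peak
#' onward, with t measured from the peak, by Levenberg-Marquardt nonlinear
#' least squares initialized from the log-linear closed form. By default the
#' fit span runs from the peak until the trace first falls below 10% of the
#' peak amplitude, capped at 1000 ms.
#'
#' @param trace a [NormalizedTrace-class].
#' @param peakFrame 0-based frame number of the peak.
#' @param fitSpanMs optional fixed fit span (ms from the peak); overrides the
#'   10%-of-peak rule.
#' @return A fit-result list: `tau` (ms), `amplitude` (fitted peak value),
#'   `t0` (peak time, ms), `rss`, `nPoints`, `converged`, `note`.
#' @export
fitDecay <- function(trace, peakFrame, fitSpanMs = NULL) {
  stopifnot(is(trace, "NormalizedTrace"))
  v <- traceValues(trace)
  tp <- timePoints(trace)
  i <- as.integer(peakFrame) + 1L
  if (i < 1L || i > length(v)) stop("peakFrame out of bounds", call. = FALSE)
  peak <- v[i]
  if (is.null(fitSpanMs)) {
    below <- which(v[i:length(v)] < 0.10 * peak)
    endIdx <- if (length(below) > 1L) i + below[below > 1L][1L] - 1L else length(v)
    if (is.na(endIdx)) endIdx <- length(v)
    endIdx <- min(endIdx, i + floor(1000 / frameInterval(trace)))
    endIdx <- min(endIdx, length(v))
  } else {
    endIdx <- min(length(v), i + floor(fitSpanMs / frameInterval(trace)))
  }
  idx <- i:endIdx
  if (length(idx) < 3L) {
    stop("decay fit needs >= 3 samples from the peak", call. = FALSE)
  }
  tt <- tp[idx] - tp[i]
  yy <- v[idx]
  n <- length(idx)

  # Log-linear initialization on the positive samples.
  pos <- yy > 0
  if (sum(pos) < 3L || peak <= 0) {
    return(fitResult(t0 = tp[i], nPoints = n, note = "non-positive segment"))
  }
  sl <- unname(coef(lm(log(yy[pos]) ~ tt[pos]))[2L])
  if (!is.finite(sl) || sl >= -1e-10) {
    return(fitResult(t0 = tp[i], rss = sum((yy - mean(yy))^2), nPoints = n,
                     note = "non-decaying segment"))
  }
  tau0 <- -1 / sl
  fit <- lmFit(c(A = peak, tau = tau0),
               function(p) yy - p[1L] * exp(-tt / p[2L]),
               lower = c(-Inf, 1e-9))
  fitResult(tau = unname(fit$par[2L]), amplitude = unname(fit$par[1L]),
            t0 = tp[i], rss = fit$rss, nPoints = n, converged = fit$converged)
}

#' Fit the saturating-exponential rise of a transient
#'
#' Locates the onset as the last frame before the peak at which the trace is
#' at or below 10% of the peak amplitude, then fits
#' \eqn{y(t) = A (1 - e^{-(t - t_0)/\tau_{rise}})} over [onset, peak], with
#' the asymptote A, the time constant and the onset time t0 all free.
#'
#' Because the trace is sampled, the frame carrying the maximum can lie past
#' the true peak, on the early decay; feeding that sample to the saturating
#' model biases the rise constant low. When at least 4 samples span the rise
#' (and `peakCorrection = TRUE`), the fit therefore uses a change-point
#' model: saturating rise up to a free peak time within the last frame
#' interval, times the event's exponential decay (constant taken from
#' [fitDecay()]) beyond it. Rises sampled by fewer than 4 frames (under
#' three frame intervals between onset and peak) are sampling-limited: they
#' are flagged unresolved and the rise constant is reported as half a frame
#' interval — the midpoint of the feasible interval (0, dt] — with
#' `converged = FALSE`.
#'
#' @param trace a [NormalizedTrace-class].
#' @param peakFrame 0-based frame number of the peak.
#' @param onsetFraction onset criterion as a fraction of peak height
#'   (default 0.10).
#' @param peakCorrection use the change-point model when enough samples are
#'   available (default TRUE).
#' @return A fit-result list as in [fitDecay()]; `t0` is the fitted onset
#'   time and `note` is `"unresolved rise"` for sampling-limited rises.
#' @export
fitRise <- function(trace, peakFrame, onsetFraction = 0.10,
                    peakCorrection = TRUE) {
  stopifnot(is(trace, "NormalizedTrace"))
  v <- traceValues(trace)
  tp <- timePoints(trace)
  i <- as.integer(peakFrame) + 1L
  if (i < 1L || i > length(v)) stop("peakFrame out of bounds", call. = FALSE)
  peak <- v[i]
  if (peak <= 0) stop("rise fit requires a positive peak", call. = FALSE)
  pre <- which(v[seq_len(i - 1L)] <= onsetFraction * peak)
  onset <- if (length(pre)) pre[length(pre)] else 1L
  idx <- onset:i
  dt <- frameInterval(trace)
  n <- length(idx)
  if (n < 4L) {
    return(fitResult(tau = dt / 2, amplitude = peak, t0 = tp[onset],
                     nPoints = n, converged = FALSE,
                     note = "unresolved rise"))
  }
  tt <- tp[idx]
  yy <- v[idx]
  span <- tp[i] - tp[onset]

  tauDecay <- NA_real_
  if (peakCorrection && n >= 4L) {
    dec <- tryCatch(fitDecay(trace, peakFrame), error = function(e) NULL)
    if (!is.null(dec) && isTRUE(dec$converged)) tauDecay <- dec$tau
  }
  if (is.finite(tauDecay)) {
    fit <- lmFit(c(A = 1.2 * peak, tau = max(span / 3, dt / 10),
                   t0 = tp[onset], ts = tp[i] - dt / 2),
                 function(p) {
                   m <- p[1L] * (1 - exp(-(pmin(tt, p[4L]) - p[3L]) / p[2L]))
                   m[tt < p[3L]] <- 0
                   late <- tt > p[4L]
                   m[late] <- p[1L] * (1 - exp(-(p[4L] - p[3L]) / p[2L])) *
                     exp(-(tt[late] - p[4L]) / tauDecay)
                   yy - m
                 },
                 lower = c(1e-12, 1e-9, tp[onset] - 10 * dt, tp[i] - dt),
                 upper = c(Inf, 100 * span, tp[i] - 1e-9, tp[i]))
  } else {
    fit <- lmFit(c(A = 1.2 * peak, tau = max(span / 3, dt / 10),
                   t0 = tp[onset]),
                 function(p) {
                   m <- p[1L] * (1 - exp(-(tt - p[3L]) / p[2L]))
                   m[tt < p[3L]] <- 0
                   yy - m
                 },
                 lower = c(1e-12, 1e-9, tp[onset] - 10 * dt),
                 upper = c(Inf, 100 * span, tp[i] - 1e-9))
  }
  fitResult(tau = unname(fit$par[2L]), amplitude = unname(fit$par[1L]),
            t0 = unname(fit$par[3L]), rss = fit$rss, nPoints = n,
            converged = fit$converged)
}

#' Fit rise and decay kinetics for every event in a table
#'
#' Applies [fitRise()] and [fitDecay()] to each detected event and fills the
#' `tau_rise`, `tau_decay`, `onset_time`, `fit_rss` and `converged` columns.
#' Events whose decay fit does not converge keep `tau_decay = NA`.
#'
#' @param trace the [NormalizedTrace-class] the events were detected on.
#' @param events an event data.frame from [detectPeaks()].
#' @param fitSpanMs optional fixed decay-fit span (ms).
#' @return The event data.frame with kinetics columns filled.
#' @export
fitEvents <- function(trace, events, fitSpanMs = NULL) {
  if (!nrow(events)) return(events)
  for (r in seq_len(nrow(events))) {
    pk <- events$peak_index[r]
    dec <- tryCatch(fitDecay(trace, pk, fitSpanMs = fitSpanMs),
                    error = function(e) fitResult(note = conditionMessage(e)))
    ris <- tryCatch(fitRise(trace, pk),
                    error = function(e) fitResult(note = conditionMessage(e)))
    events$tau_decay[r] <- if (isTRUE(dec$converged)) dec$tau else NA_real_
    events$tau_rise[r] <- ris$tau
    events$onset_time[r] <- ris$t0
    events$fit_rss[r] <- dec$rss
    events$converged[r] <- isTRUE(dec$converged)
  }
  events
}

#' Rate-form single-exponential decay fit
#'
#' The benchmark-mode decay analysis: fits \eqn{\Delta F/F = A_0 e^{b t}}
#' with t in seconds, expecting b < 0, and reports the intercept at time 0
#' (\eqn{A_0}) together with the decay time constant \eqn{\tau = 1000 / (-b)}
#' ms.
#'
#' @param values dF/F samples.
#' @param timesS sample times in seconds (the benchmark convention).
#' @return A list: `A0`, `b` (1/s), `tau_ms`, `rss`, `nPoints`, `converged`.
#' @examples
#' t <- seq(0.014828, 0.499193, length.out = 147)
#' fitDecayRateForm(0.3 * exp(-20 * t), t)$tau_ms   # 50
#' @export
fitDecayRateForm <- function(values, timesS) {
  if (length(values) < 3L || length(values) != length(timesS)) {
    stop("need >= 3 samples with matching times", call. = FALSE)
  }
  assertFiniteVector(values, "values")
  pos <- values > 0
  if (sum(pos) < 3L) stop("non-decaying segment: too few positive samples",
                          call. = FALSE)
  cf <- coef(lm(log(values[pos]) ~ timesS[pos]))
  b0 <- unname(cf[2L]); A0 <- exp(unname(cf[1L]))
  fit <- lmFit(c(A = A0, b = b0),
               function(p) values - p[1L] * exp(p[2L] * timesS))
  b <- unname(fit$par[2L])
  if (b >= 0) stop("non-decaying segment: fitted rate b >= 0", call. = FALSE)
  list(A0 = unname(fit$par[1L]), b = b, tau_ms = 1000 / (-b), rss = fit$rss,
       nPoints = length(values), converged = fit$converged)
}

#' Align single-stimulus sweeps to the first rise and average
#'
#' For each sweep, the first-rise frame is the first post-stimulus frame
#' exceeding `riseThreshold` (default: twice the standard deviation of the
#' sweep's pre-stimulus segment). Sweeps are shifted so that frame sits half
#' a sampling interval (+dt/2) after the stimulus — at dt = 3.295 ms the
#' first rise lands 1.6475 ms after the stimulus — and averaged pointwise
#' over their common overlap. Sweeps with no supra-threshold post-stimulus
#' frame are excluded with a warning.
#'
#' @param sweeps list of numeric sweep vectors sampled at a common interval.
#' @param stimulusIndex 1-based frame index of the stimulus within each sweep
#'   (scalar or one per sweep).
#' @param frameIntervalMs sampling interval dt (ms).
#' @param riseThreshold threshold for the first rise; `NULL` for the
#'   per-sweep 2-sigma default.
#' @return A list: `values` (the averaged sweep), `times` (ms relative to the
#'   stimulus; the first-rise sample sits at +dt/2), `nSweeps` used,
#'   `firstRiseFrames`, and `excluded` sweep indices.
#' @export
alignAndAverage <- function(sweeps, stimulusIndex, frameIntervalMs,
                            riseThreshold = NULL) {
  if (!length(sweeps)) stop("need >= 1 sweep", call. = FALSE)
  stimulusIndex <- rep_len(as.integer(stimulusIndex), length(sweeps))
  firstRise <- integer(length(sweeps))
  for (s in seq_along(sweeps)) {
    v <- sweeps[[s]]
    si <- stimulusIndex[s]
    if (si < 1L || si > length(v)) stop("stimulusIndex outside sweep", call. = FALSE)
    thr <- riseThreshold
    if (is.null(thr)) {
      preSd <- if (si > 2L) sd(v[seq_len(si - 1L)]) else 0
      thr <- 2 * preSd
    }
    post <- which(v[si:length(v)] > thr)
    firstRise[s] <- if (length(post)) si + post[1L] - 1L else NA_integer_
  }
  excluded <- which(is.na(firstRise))
  if (length(excluded)) {
    warning(sprintf("excluding %d sweep(s) with no supra-threshold rise",
                    length(excluded)))
  }
  use <- setdiff(seq_along(sweeps), excluded)
  if (!length(use)) stop("no usable sweeps after exclusion", call. = FALSE)
  nBefore <- min(firstRise[use] - 1L)
  nAfter <- min(vapply(use, function(s) length(sweeps[[s]]) - firstRise[s],
                       integer(1)))
  mat <- vapply(use, function(s) {
    f <- firstRise[s]
    sweeps[[s]][(f - nBefore):(f + nAfter)]
  }, numeric(nBefore + nAfter + 1L))
  avg <- rowMeans(as.matrix(mat))
  times <- frameIntervalMs / 2 + (-nBefore:nAfter) * frameIntervalMs
  list(values = avg, times = times, nSweeps = length(use),
       firstRiseFrames = firstRise, excluded = excluded)
}
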