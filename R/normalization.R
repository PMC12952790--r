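#' @include AllClasses.R
NULL

#' Baseline-estimation parameters
#'
#' Parameters for the sliding-window baseline estimator. The default window is
#' 101 frames (50 before and after each time point). Two estimators are
#' available: the pth percentile of the window values (default p = 30, the
#' convention for dF/F baselines) and the mean of the lowest fraction of
#' window values (default the lowest 10%, the convention for ratiometric R0
#' baselines).
#'
#' @param window odd window length in frames, >= 3 (default 101).
#' @param method `"percentile"` or `"lowest_fraction"`.
#' @param percentile percentile in (0, 100) for `method = "percentile"`
#'   (default 30). Linear-interpolation convention: the value at sorted index
#'   `p/100 * (m - 1)` (0-based) of the m window values.
#' @param fraction fraction in (0, 1] for `method = "lowest_fraction"`
#'   (default 0.10); the baseline is the mean of the `ceiling(fraction * m)`
#'   smallest window values.
#' @param smoothWindow moving-average window (frames) applied to the
#'   reference channel before ratio formation in [normalizeDRR()]; 1 = no
#'   smoothing.
#' @return A validated list of class `"BaselineParams"`.
#' @export
baselineParams <- function(window = 101L, method = c("percentile", "lowest_fraction"),
                           percentile = 30, fraction = 0.10, smoothWindow = 1L) {
  method <- match.arg(method)
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) {
    stop("window must be an odd integer >= 3", call. = FALSE)
  }
  if (!is.finite(percentile) || percentile <= 0 || percentile >= 100) {
    stop("percentile must lie in (0, 100)", call. = FALSE)
  }
  if (!is.finite(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(smoothWindow) || smoothWindow < 1) {
    stop("smoothWindow must be >= 1", call. = FALSE)
  }
  structure(list(window = window, method = method, percentile = percentile,
                 fraction = fraction, smoothWindow = as.integer(smoothWindow),
                 edge_policy = "truncate"),
            class = "BaselineParams")
}

# Linear-interpolation percentile of a sorted vector: value at 0-based index
# p/100 * (m - 1). Matches the common "linear" definition.
interpPercentile <- function(sorted, p) {
  m <- length(sorted)
  if (m == 1L) return(sorted[1L])
  h <- p / 100 * (m - 1)
  lo <- floor(h)
  frac <- h - lo
  v <- sorted[lo + 1L]
  if (frac > 0) v <- v + frac * (sorted[lo + 2L] - v)
  v
}

#' Sliding-window baseline estimation
#'
#' Estimates a time-varying baseline F0(t) (or R0(t)) by sliding a centered
#' window across the trace and taking, per frame, either a percentile of the
#' window values or the mean of the lowest fraction of them. Windows are
#' truncated at the array ends (no padding), so the output has the input's
#' length and short traces are handled without error.
#'
#' @param values numeric intensity (or ratio) series, all finite.
#' @param params a [baselineParams()] object.
#' @return Numeric baseline, same length as `values`.
#' @examples
#' b <- slidingBaseline(rep(5, 20), baselineParams(window = 5))
#' all(b == 5)
#' @export
slidingBaseline <- function(values, params = baselineParams()) {
  assertFiniteVector(values, "values")
  stopifnot(inherits(params, "BaselineParams"))
  n <- length(values)
  h <- (params$window - 1L) %/% 2L
  isPct <- params$method == "percentile"
  p <- params$percentile
  frac <- params$fraction
  out <- numeric(n)
  for (k in seq_len(n)) {
    lo <- max(1L, k - h)
    hi <- min(n, k + h)
    w <- sort.int(values[lo:hi], method = "quick")
    if (isPct) {
      out[k] <- interpPercentile(w, p)
    } else {
      nl <- ceiling(frac * length(w))
      out[k] <- mean(w[seq_len(nl)])
    }
  }
  out
}

#' Normalize a raw recording to dF/F
#'
#' Computes the fractional fluorescence change
#' \deqn{\Delta F/F(t) = [F(t) - F_0(t)] / F_0(t)}
#' against the sliding-window percentile baseline F0(t). The slow baseline
#' drift caused by photobleaching is absorbed into F0(t), so no separate
#' bleach correction is needed for mini analysis.
#'
#' @param rec a raw [Recording-class].
#' @param params a [baselineParams()] object (default: 101-frame window, 30th
#'   percentile).
#' @return A [NormalizedTrace-class] with `mode = "dff"`.
#' @export
normalizeDFF <- function(rec, params = baselineParams()) {
  stopifnot(is(rec, "Recording"))
  if (traceMode(rec) != "raw") {
    stop("normalizeDFF expects a raw recording; this one is already normalized",
         call. = FALSE)
  }
  f <- signalValues(rec)
  f0 <- slidingBaseline(f, params)
  bad <- which(f0 <= 0)
  if (length(bad)) {
    stop(sprintf("baseline F0 <= 0 at frame %d (0-based %d); dF/F undefined",
                 bad[1L], bad[1L] - 1L), call. = FALSE)
  }
  new("NormalizedTrace", meta = acqMeta(rec), roiId = roiId(rec),
      values = (f - f0) / f0, baseline = f0, raw = f, mode = "dff",
      params = unclass(params))
}

#' Centered moving-average smoothing
#'
#' Smooths a series with a centered moving average whose window truncates at
#' the array ends; `window = 1` returns the input unchanged. Used on the
#' reference channel before ratio formation.
#'
#' @param x numeric series.
#' @param window window length in frames (>= 1).
#' @return Smoothed series, same length.
#' @examples
#' smoothReference(c(0, 3, 0), 3)   # 1.5 1.0 1.5
#' @export
smoothReference <- function(x, window) {
  if (!is.numeric(window) || length(window) != 1L || window < 1) {
    stop("window must be a single value >= 1", call. = FALSE)
  }
  window <- as.integer(window)
  if (window == 1L) return(x)
  n <- length(x)
  hl <- (window - 1L) %/% 2L        # frames before the center
  hr <- window - 1L - hl            # frames after (even windows lean forward)
  cs <- cumsum(c(0, x))
  lo <- pmax(1L, seq_len(n) - hl)
  hi <- pmin(n, seq_len(n) + hr)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Normalize a dual-channel recording to ratiometric dR/R
#'
#' Forms the per-frame ratio \eqn{R(t) = F_{sig}(t) / F_{ref}(t)} between the
#' calcium indicator and the co-expressed calcium-insensitive reference
#' fluorophore, estimates the baseline ratio R0(t) with the sliding-window
#' estimator (by default the mean of the lowest 10% of ratio values in a
#' 101-frame window), and reports
#' \deqn{\Delta R/R(t) = [R(t) - R_0(t)] / R_0(t).}
#' Because both channels share illumination and expression-level gains, the
#' ratio cancels those common factors. The reference may be smoothed with a
#' moving average (`params$smoothWindow`) before division to suppress
#' high-frequency reference noise.
#'
#' @param rec a raw [Recording-class] with a reference channel attached.
#' @param params a [baselineParams()]; default 101-frame window with the
#'   lowest-10% estimator.
#' @return A [NormalizedTrace-class] with `mode = "drr"`; its `raw` slot holds
#'   the ratio series R(t).
#' @export
normalizeDRR <- function(rec,
                         params = baselineParams(method = "lowest_fraction")) {
  stopifnot(is(rec, "Recording"))
  if (!hasReference(rec)) {
    stop("normalizeDRR requires a reference channel (attachReference)",
         call. = FALSE)
  }
  if (traceMode(rec) != "raw") {
    stop("normalizeDRR expects raw intensities", call. = FALSE)
  }
  ref <- smoothReference(referenceValues(rec), params$smoothWindow)
  bad <- which(ref <= 0)
  if (length(bad)) {
    stop(sprintf("smoothed reference <= 0 at frame %d; ratio undefined", bad[1L]),
         call. = FALSE)
  }
  r <- signalValues(rec) / ref
  r0 <- slidingBaseline(r, params)
  bad <- which(r0 <= 0)
  if (length(bad)) {
    stop(sprintf("baseline R0 <= 0 at frame %d", bad[1L]), call. = FALSE)
  }
  new("NormalizedTrace", meta = acqMeta(rec), roiId = roiId(rec),
      values = (r - r0) / r0, baseline = r0, raw = r, mode = "drr",
      params = unclass(params))
}

#' Linear photobleaching correction from pre-stimulus windows
#'
#' Estimates the slow bleaching trend by averaging the fluorescence in a short
#' window (default 100 ms) preceding each stimulus of a low-frequency block,
#' regressing those window means on the window-center times by ordinary least
#' squares, and detrending the trace with the fitted slope. The additive
#' correction `F(t) - slope * (t - t_c1)` anchors the trace at the first
#' window's center `t_c1`, leaving that window's mean unchanged; a
#' multiplicative variant divides by the fitted line rescaled to 1 at `t_c1`.
#'
#' @param rec a raw [Recording-class].
#' @param protocol a [StimulusProtocol-class]; all stimuli of its first block
#'   (or of `block`) define the pre-stimulus windows.
#' @param windowMs pre-stimulus window length (ms, default 100).
#' @param block optional block label (default: first block).
#' @param variant `"additive"` (default) or `"multiplicative"`.
#' @return A list with `recording` (the corrected [Recording-class]) and
#'   `fit` (slope in intensity/ms, intercept at t = 0, and the window means).
#' @export
bleachCorrect <- function(rec, protocol, windowMs = 100, block = NULL,
                          variant = c("additive", "multiplicative")) {
  variant <- match.arg(variant)
  stopifnot(is(rec, "Recording"), is(protocol, "StimulusProtocol"))
  if (is.null(block)) block <- blockLabels(protocol)[1L]
  stim <- stimulusTimes(protocol, block)
  if (length(stim) < 2L) {
    stop("bleach correction needs >= 2 stimuli in the block", call. = FALSE)
  }
  tp <- timePoints(rec)
  f <- signalValues(rec)
  centers <- means <- numeric(0)
  for (s in stim) {
    inWin <- tp >= s - windowMs & tp < s
    if (!any(inWin)) {
      stop(sprintf("empty pre-stimulus window before stimulus at %.6g ms", s),
           call. = FALSE)
    }
    centers <- c(centers, s - windowMs / 2)
    means <- c(means, mean(f[inWin]))
  }
  if (length(unique(centers)) < 2L) {
    stop("need >= 2 distinct pre-stimulus windows", call. = FALSE)
  }
  fit <- lm(means ~ centers)
  slope <- unname(coef(fit)[2L])       # intensity units per ms
  intercept <- unname(coef(fit)[1L])
  corrected <- if (variant == "additive") {
    f - slope * (tp - centers[1L])
  } else {
    line <- intercept + slope * tp
    anchor <- intercept + slope * centers[1L]
    if (any(line <= 0)) stop("fitted bleach line crosses zero", call. = FALSE)
    f * anchor / line
  }
  out <- recording(corrected, meta = acqMeta(rec), roiId = roiId(rec),
                   reference = if (hasReference(rec)) referenceValues(rec)
                               else numeric(0),
                   mode = traceMode(rec))
  list(recording = out,
       fit = list(slope = slope, intercept = intercept,
                  window_means = data.frame(center_time = centers,
                                            mean_intensity = means)))
}

#' Rest-window dF/F normalization
#'
#' The benchmark-mode normalization: dF/F is computed against a single
#' constant baseline, the mean fluorescence over the `restMs` (default
#' 100 ms) preceding the first stimulus —
#' \eqn{(F_{stim} - F_{rest}) / F_{rest}}. The rest window is half-open:
#' frames at exactly `firstStimTime` are excluded.
#'
#' @param rec a raw [Recording-class] (typically bleach-corrected first).
#' @param firstStimTime time of the first stimulus (ms).
#' @param restMs rest-window length (ms, default 100).
#' @return A [NormalizedTrace-class] with constant baseline and `mode = "dff"`.
#' @export
restNormalize <- function(rec, firstStimTime, restMs = 100) {
  stopifnot(is(rec, "Recording"))
  tp <- timePoints(rec)
  f <- signalValues(rec)
  inWin <- tp >= firstStimTime - restMs & tp < firstStimTime
  if (!any(inWin)) {
    stop(sprintf("no frames in the rest window [%.6g, %.6g) ms",
                 firstStimTime - restMs, firstStimTime), call. = FALSE)
  }
  fRest <- mean(f[inWin])
  if (fRest <= 0) stop("rest-window mean fluorescence must be > 0", call. = FALSE)
  new("NormalizedTrace", meta = acqMeta(rec), roiId = roiId(rec),
      values = (f - fRest) / fRest, baseline = rep(fRest, length(f)), raw = f,
      mode = "dff",
      params = list(method = "rest_window", rest_ms = restMs,
                    first_stim_time = firstStimTime))
}
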