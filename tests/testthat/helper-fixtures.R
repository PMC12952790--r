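# Shared helpers: small programmatic fixtures and independent oracles.

# A NormalizedTrace built directly from a value vector (baseline 1, raw = 1+v).
normTrace <- function(values, frameRate = 100, mode = "dff", startTime = 0) {
  new("NormalizedTrace",
      meta = acquisitionMeta(frameRate = frameRate, startTime = startTime),
      roiId = "test", values = as.numeric(values),
      baseline = rep(1, length(values)), raw = 1 + as.numeric(values),
      mode = mode, params = list())
}

# Scale a NormalizedTrace's values by c > 0 (baseline unchanged).
scaleTrace <- function(trace, c) {
  v <- traceValues(trace) * c
  new("NormalizedTrace", meta = acqMeta(trace), roiId = roiId(trace),
      values = v, baseline = baselineValues(trace),
      raw = baselineValues(trace) * (1 + v), mode = traceMode(trace),
      params = normParams(trace))
}

# Independent sliding-baseline oracle: per-index sort/select using
# stats::quantile (type 7) and a direct lowest-k mean.
bruteBaseline <- function(values, window, method, percentile = 30,
                          fraction = 0.10) {
  n <- length(values)
  h <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(k) {
    w <- values[max(1L, k - h):min(n, k + h)]
    if (method == "percentile") {
      quantile(w, percentile / 100, type = 7, names = FALSE)
    } else {
      s <- sort(w)
      mean(s[seq_len(ceiling(fraction * length(s)))])
    }
  }, numeric(1))
}

# A triangular transient of given peak height centered at frame `at`
# (1-based), half-width `hw` frames, on a zero baseline of length n.
triangleTrace <- function(n, at, height, hw, frameRate = 100) {
  v <- numeric(n)
  for (k in seq(-hw, hw)) {
    i <- at + k
    if (i >= 1 && i <= n) v[i] <- height * (1 - abs(k) / hw)
  }
  normTrace(v, frameRate = frameRate)
}

# Independent greedy globally-nearest matcher (index-based reimplementation).
bruteMatch <- function(ephTimes, optTimes, tol) {
  pairs <- list()
  usedE <- rep(FALSE, length(ephTimes))
  usedO <- rep(FALSE, length(optTimes))
  repeat {
    best <- NULL
    for (i in seq_along(ephTimes)) for (j in seq_along(optTimes)) {
      if (usedE[i] || usedO[j]) next
      d <- abs(ephTimes[i] - optTimes[j])
      if (d > tol) next
      if (is.null(best) || d < best$d - 1e-12 ||
          (abs(d - best$d) <= 1e-12 && ephTimes[i] < ephTimes[best$i])) {
        best <- list(i = i, j = j, d = d)
      }
    }
    if (is.null(best)) break
    usedE[best$i] <- TRUE
    usedO[best$j] <- TRUE
    pairs[[length(pairs) + 1L]] <- best
  }
  pairs
}

tmpCsv <- function(df) {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE)
  f
}
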