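test_that("decay fits recover exact exponentials to <0.1%", {
  tp <- seq(0, 990, by = 10)
  v <- 0.5 * exp(-tp / 50)
  tr <- normTrace(v)
  fit <- fitDecay(tr, 0)
  expect_true(fit$converged)
  expect_lt(abs(fit$tau - 50) / 50, 0.001)
  expect_lt(abs(fit$amplitude - 0.5) / 0.5, 0.001)
  # agrees with the log-linear closed form on noiseless data
  logl <- -1 / coef(lm(log(v[1:50]) ~ tp[1:50]))[[2]]
  expect_lt(abs(fit$tau - logl) / logl, 0.001)
})

test_that("decay fit is scale-equivariant", {
  tp <- seq(0, 990, by = 10)
  tr <- normTrace(0.4 * exp(-tp / 80))
  f1 <- fitDecay(tr, 0)
  f2 <- fitDecay(scaleTrace(tr, 3), 0)
  expect_equal(f2$tau, f1$tau, tolerance = 1e-9)
  expect_equal(f2$amplitude, 3 * f1$amplitude, tolerance = 1e-9)
})

test_that("degenerate decay segments are flagged, not fitted", {
  tr <- normTrace(rep(0.5, 50))
  fit <- fitDecay(tr, 0)
  expect_false(fit$converged)
  expect_true(is.na(fit$tau))
  expect_error(fitDecay(normTrace(c(0.5, 0.4, 0.3)), 2), ">= 3 samples")
})

test_that("rise fits recover the time constant on well-sampled rises", {
  # saturating rise, tau = 14 ms, 1 kHz sampling
  tp <- seq(0, 120, by = 1)
  v <- 0.6 * (1 - exp(-tp / 14))
  tr <- normTrace(c(rep(0, 20), v), frameRate = 1000)
  fit <- fitRise(tr, length(tp) + 19)
  expect_true(fit$converged)
  expect_lt(abs(fit$tau - 14) / 14, 0.01)
})

test_that("single-frame rises are flagged unresolved and bounded by dt", {
  v <- c(rep(0, 30), 1, exp(-(1:30) / 8))
  tr <- normTrace(v, frameRate = 100)
  fit <- fitRise(tr, 30)
  expect_false(fit$converged)
  expect_lte(fit$tau, 10)
})

test_that("rise fit attains the least-squares minimum on a linear ramp", {
  v <- c(rep(0, 5), seq(0.1, 1, length.out = 10), exp(-(1:20) / 5))
  tr <- normTrace(v, frameRate = 100)
  fit <- fitRise(tr, 14, peakCorrection = FALSE)
  expect_true(fit$converged)
  expect_gt(fit$tau, 0)
  # coarse-to-fine grid-search oracle over (A, tau, t0)
  tp <- timePoints(tr)
  idx <- which(v <= 0.1 * v[15])
  onset <- max(idx[idx < 15])
  tt <- tp[onset:15]; yy <- v[onset:15]
  rssOf <- function(A, tau, t0) {
    m <- A * (1 - exp(-(tt - t0) / tau)); m[tt < t0] <- 0
    sum((yy - m)^2)
  }
  best <- Inf
  for (A in seq(0.5, 3, length.out = 40))
    for (tau in seq(1, 300, length.out = 60))
      for (t0 in seq(tp[onset] - 20, tp[15] - 1, length.out = 30))
        best <- min(best, rssOf(A, tau, t0))
  expect_lte(fit$rss, best + 1e-6)
})

test_that("rate-form benchmark fit returns A0 and tau = 1000/(-b)", {
  t <- seq(0.014828, 0.499193, length.out = 147)
  v <- 0.3 * exp(-20 * t)
  fit <- fitDecayRateForm(v, t)
  expect_equal(fit$A0, 0.3, tolerance = 1e-6)
  expect_equal(fit$tau_ms, 50, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
  expect_equal(fit$nPoints, 147)
  # growing segments are refused
  expect_error(fitDecayRateForm(0.1 * exp(3 * t), t), "non-decaying")
})

test_that("sweep alignment puts the first rise half a frame after the stimulus", {
  dt <- 3.295
  sw <- lapply(1:10, function(k) {
    v <- numeric(300)
    v[101:160] <- 0.4 * exp(-(0:59) * dt / 40)
    v
  })
  aa <- alignAndAverage(sw, stimulusIndex = 95, frameIntervalMs = dt,
                        riseThreshold = 0.01)
  expect_equal(aa$nSweeps, 10)
  # the first-rise sample sits at +dt/2 = 1.6475 ms
  riseIdx <- which.min(abs(aa$times - dt / 2))
  expect_equal(aa$times[riseIdx], 1.6475, tolerance = 1e-9)
  expect_equal(aa$values[riseIdx], 0.4, tolerance = 1e-12)
  # identical sweeps average to any single sweep over the overlap
  expect_equal(max(aa$values), max(sw[[1]]))
})

test_that("alignment cancels integer-frame offsets between sweeps", {
  base <- numeric(200)
  base[81:140] <- 0.5 * exp(-(0:59) / 10)
  shifted <- c(numeric(1), base[1:199])   # one frame later
  aa <- alignAndAverage(list(base, shifted), stimulusIndex = 70,
                        frameIntervalMs = 10, riseThreshold = 0.05)
  expect_equal(max(aa$values), 0.5, tolerance = 1e-12)
  # a flat sweep is excluded with a warning; all-flat input errors
  expect_warning(
    aa2 <- alignAndAverage(list(base, numeric(200)), stimulusIndex = 70,
                           frameIntervalMs = 10, riseThreshold = 0.05),
    "excluding")
  expect_equal(aa2$nSweeps, 1)
  expect_error(
    suppressWarnings(alignAndAverage(list(numeric(200)), stimulusIndex = 70,
                                     frameIntervalMs = 10,
                                     riseThreshold = 0.05)),
    "no usable sweeps")
})

test_that("event tables gain kinetics columns from fitEvents", {
  sim <- simulateEvokedRecording(
    simSpec(durationMs = 15000, frameRate = 100, baselineF = 100,
            amplitude = 0.5, tauRise = 14, tauDecay = 67, miniRate = 0,
            noiseSigma = 0.5, bleach = 1, seed = 2),
    protocolFromBlocks("sparse", 0.5, 5, 2000), gains = rep(1, 5))
  tr <- normalizeDFF(sim$recording)
  ev <- detectPeaks(tr, detectionSettings(threshold = 0.2, minDistance = 200))
  ev <- fitEvents(tr, ev)
  expect_equal(nrow(ev), 5)
  expect_true(all(is.finite(ev$tau_decay)))
  expect_true(all(ev$tau_rise > 0))
  expect_true(all(ev$onset_time <= ev$peak_time))
  expect_lt(abs(median(ev$tau_decay) - 67) / 67, 0.10)
})
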