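test_that("threshold detection finds isolated transients", {
  # triangular transient peaking at 1.0 at t = 500 ms on a zero trace
  tr <- triangleTrace(200, at = 51, height = 1, hw = 10)
  ev <- detectPeaks(tr, detectionSettings(threshold = 0.5))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$peak_time, 500)
  expect_equal(ev$amplitude, 1)
  expect_equal(ev$source, "auto")
  # raising the threshold above the peak removes it
  expect_equal(nrow(detectPeaks(tr, detectionSettings(threshold = 1.5))), 0)
})

test_that("minimum-distance suppression keeps the larger peak", {
  v <- numeric(200)
  v[41] <- 0.8   # t = 400 ms
  v[44] <- 1.0   # t = 430 ms
  tr <- normTrace(v)
  ev <- detectPeaks(tr, detectionSettings(threshold = 0.5, minDistance = 50))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$peak_time, 430)
  # without suppression both peaks survive
  ev2 <- detectPeaks(tr, detectionSettings(threshold = 0.5, minDistance = 0))
  expect_equal(ev2$peak_time, c(400, 430))
})

test_that("width-at-half-height filters single-frame spikes", {
  v <- numeric(100)
  v[30] <- 1                      # 1-frame spike
  v[60:64] <- c(0.6, 0.9, 1, 0.9, 0.6)  # broad peak, width 5 at half height
  tr <- normTrace(v)
  ev <- detectPeaks(tr, detectionSettings(threshold = 0.5, minWidth = 3))
  expect_equal(ev$peak_time, 610)
})

test_that("plateau maxima resolve to the plateau's first frame", {
  v <- numeric(50)
  v[20:22] <- 1
  ev <- detectPeaks(normTrace(v), detectionSettings(threshold = 0.5))
  expect_equal(ev$peak_index, 19L)   # 0-based frame of the plateau start
})

test_that("manual nearest-peak selection obeys radius and tie rules", {
  v <- numeric(100)
  v[31] <- 0.4   # t = 300
  v[51] <- 0.2   # t = 500 (below any reasonable auto threshold)
  tr <- normTrace(v)
  s <- detectionSettings(threshold = 10, searchRadius = 200)
  expect_equal(nearestPeak(tr, 480, s)$peak_time, 500)
  # equidistant click resolves to the earlier peak
  expect_equal(nearestPeak(tr, 400, s)$peak_time, 300)
  expect_equal(nearestPeak(tr, 480, s)$source, "manual")
  # monotone segment: nothing to rescue
  ramp <- normTrace(seq(0, 1, length.out = 100))
  expect_error(nearestPeak(ramp, 500, s), "no local maximum")
})

test_that("amplitude measurement supports zero-based and local-base modes", {
  v <- numeric(100)
  v[41] <- 0.58
  tr <- normTrace(v)
  expect_equal(measureAmplitude(tr, 40, "from_zero"), 0.58)
  expect_equal(measureAmplitude(tr, 40, "from_local_base"), 0.58)
  # a peak riding on a 0.3 pedestal from an unresolved earlier event
  v2 <- rep(0.3, 100)
  v2[1:10] <- 0
  v2[61] <- 1.0
  tr2 <- normTrace(v2)
  expect_equal(measureAmplitude(tr2, 60, "from_local_base", spanMs = 200), 0.7)
  expect_equal(measureAmplitude(tr2, 60, "from_zero"), 1.0)
})

test_that("detection is deterministic and monotone in its criteria", {
  set.seed(21)
  sim <- simulateQuantalRecording(simSpec(durationMs = 30000, frameRate = 100,
                                          miniRate = 1, amplitude = 0.4,
                                          noiseSigma = 2, seed = 77))
  tr <- normalizeDFF(sim$recording)
  s0 <- detectionSettings(threshold = 0.1, minDistance = 50)
  expect_identical(detectPeaks(tr, s0), detectPeaks(tr, s0))
  nPrev <- Inf
  for (thr in c(0.05, 0.1, 0.2, 0.3, 0.5)) {
    n <- nrow(detectPeaks(tr, detectionSettings(threshold = thr,
                                                minDistance = 50)))
    expect_lte(n, nPrev)
    nPrev <- n
  }
  nPrev <- Inf
  for (d in c(0, 20, 50, 100, 200)) {
    n <- nrow(detectPeaks(tr, detectionSettings(threshold = 0.1,
                                                minDistance = d)))
    expect_lte(n, nPrev)
    nPrev <- n
  }
})

test_that("unnormalized input is rejected", {
  rec <- recording(rnorm(100, 100), 100)
  expect_error(detectPeaks(rec, detectionSettings(threshold = 0.1)))
})
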