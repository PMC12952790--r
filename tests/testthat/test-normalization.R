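test_that("sliding baseline reproduces closed-form window statistics", {
  # constant trace: baseline equals the constant everywhere, any method
  expect_equal(slidingBaseline(rep(7, 25), baselineParams(window = 7)),
               rep(7, 25))
  expect_equal(slidingBaseline(rep(7, 25),
                               baselineParams(window = 7,
                                              method = "lowest_fraction")),
               rep(7, 25))
  # permutation of 1..101, 30th percentile at the full-window center:
  # linear-interpolation index 0.30 * 100 = 30 (0-based) -> value 31
  set.seed(11)
  w <- sample(1:101)
  expect_equal(slidingBaseline(w, baselineParams(window = 101))[51], 31)
  # permutation of 1..100: mean of the lowest ceiling(0.1*100) = 10 values
  set.seed(12)
  w2 <- sample(1:100)
  b <- slidingBaseline(w2, baselineParams(window = 199,
                                          method = "lowest_fraction"))
  expect_equal(b[50], mean(1:10))
})

test_that("sliding baseline matches the brute-force per-window oracle", {
  set.seed(101)
  for (rep in 1:60) {
    n <- sample(10:300, 1)
    w <- sample(seq(3, 101, by = 2), 1)
    p <- runif(1, 5, 95)
    fr <- runif(1, 0.05, 0.5)
    v <- rnorm(n, 100, 10)
    expect_equal(slidingBaseline(v, baselineParams(window = w, percentile = p)),
                 bruteBaseline(v, w, "percentile", percentile = p),
                 tolerance = 1e-12)
    expect_identical(
      slidingBaseline(v, baselineParams(window = w, method = "lowest_fraction",
                                        fraction = fr)),
      bruteBaseline(v, w, "lowest_fraction", fraction = fr))
  }
})

test_that("sliding baseline is shift-equivariant", {
  set.seed(7)
  v <- rnorm(120, 50, 5)
  for (m in c("percentile", "lowest_fraction")) {
    p <- baselineParams(window = 21, method = m)
    expect_equal(slidingBaseline(v + 13.5, p), slidingBaseline(v, p) + 13.5,
                 tolerance = 1e-10)
  }
})

test_that("dF/F normalization follows (F - F0)/F0 and round-trips", {
  rec <- recording(rep(100, 50), 100)
  tr <- normalizeDFF(rec)
  expect_equal(traceValues(tr), rep(0, 50))
  # flat trace with a brief transient: flat region baseline 100, peak dF/F 0.5
  v <- rep(100, 300)
  v[150:154] <- 150
  tr2 <- normalizeDFF(recording(v, 100))
  expect_equal(baselineValues(tr2)[1:100], rep(100, 100))
  expect_equal(max(traceValues(tr2)), 0.5)
  # denormalization recovers the raw trace
  set.seed(3)
  v3 <- rnorm(200, 80, 4)
  tr3 <- normalizeDFF(recording(v3, 100))
  expect_equal(baselineValues(tr3) * (1 + traceValues(tr3)), v3,
               tolerance = 1e-12)
  # non-positive baseline is an error naming a frame
  expect_error(normalizeDFF(recording(c(-5, -5, -5, -5), 100)), "frame")
})

test_that("reference smoothing is a truncated centered moving average", {
  expect_equal(smoothReference(c(0, 3, 0), 3), c(1.5, 1.0, 1.5))
  set.seed(4)
  x <- rnorm(30)
  expect_identical(smoothReference(x, 1), x)
  expect_equal(smoothReference(rep(2.5, 40), 9), rep(2.5, 40))
  expect_error(smoothReference(x, 0), "window")
})

test_that("ratiometric dR/R cancels common gain and recovers event peaks", {
  set.seed(5)
  ref <- rnorm(200, 50, 0.5)
  rec <- recording(2 * ref, 100, reference = ref)
  tr <- normalizeDRR(rec)
  expect_equal(traceValues(tr), rep(0, 200), tolerance = 1e-12)
  expect_equal(rawValues(tr), rep(2, 200), tolerance = 1e-12)

  # common multiplicative bleach of both channels leaves dR/R at zero
  bleach <- 0.97^(seq(0, 1, length.out = 300))
  rec2 <- recording(120 * bleach, 100, reference = 60 * bleach)
  expect_equal(traceValues(normalizeDRR(rec2)), rep(0, 300), tolerance = 1e-12)

  # noiseless dual-channel event with true dR/R peak 0.4
  sim <- simulateEvokedRecording(
    simSpec(durationMs = 5000, frameRate = 1000, baselineF = 100,
            amplitude = 0.4, tauRise = 14, tauDecay = 67, miniRate = 0,
            noiseSigma = 0, bleach = 1,
            reference = list(baselineF = 50, noiseSigma = 0, bleach = 1),
            seed = 1),
    protocolFromBlocks("one", 1, 1, 2500), gains = 1)
  tr3 <- normalizeDRR(sim$recording)
  expect_equal(max(traceValues(tr3)), 0.4, tolerance = 0.02 * 0.4)

  expect_error(normalizeDRR(recording(1:10, 100)), "reference")
})

test_that("bleach correction recovers an injected linear trend", {
  proto <- protocolFromBlocks("1Hz", 1, 10, 1000)
  tp <- seq(0, 10999, by = 10)
  f <- 100 - 0.5 * (tp / 1000)
  out <- bleachCorrect(recording(f, 100), proto)
  expect_equal(out$fit$slope * 1000, -0.5, tolerance = 1e-9)
  corrected <- signalValues(out$recording)
  expect_lt(diff(range(corrected)), 1e-9)

  # constant trace: slope 0, trace unchanged
  out2 <- bleachCorrect(recording(rep(80, 1100), 100), proto)
  expect_equal(out2$fit$slope, 0, tolerance = 1e-12)
  expect_equal(signalValues(out2$recording), rep(80, 1100))

  # a single stimulus cannot anchor a trend
  proto1 <- protocolFromBlocks("one", 1, 1, 1000)
  expect_error(bleachCorrect(recording(f, 100), proto1), ">= 2 stimuli")
})

test_that("bleach correction recovers slope within 1% under 1% noise", {
  proto <- protocolFromBlocks("1Hz", 1, 10, 1000)
  tp <- seq(0, 10999, by = 10)
  slopes <- vapply(1:50, function(s) {
    set.seed(s)
    f <- 100 - 0.8 * (tp / 1000) + rnorm(length(tp), 0, 1)
    bleachCorrect(recording(f, 100), proto)$fit$slope * 1000
  }, numeric(1))
  expect_lt(abs(mean(slopes) - (-0.8)) / 0.8, 0.01)
})

test_that("rest-window normalization uses a half-open 100 ms window", {
  tp <- seq(0, 999, by = 10)
  f <- rep(100, 100)
  f[tp >= 500] <- 120
  tr <- restNormalize(recording(f, 100), firstStimTime = 500)
  # frames at exactly t = 500 are excluded from the rest window
  expect_equal(unique(baselineValues(tr)), 100)
  expect_equal(max(traceValues(tr)), 0.2)
  expect_equal(traceValues(restNormalize(recording(rep(55, 100), 100), 500)),
               rep(0, 100))
  expect_error(restNormalize(recording(f, 100), firstStimTime = 0), "rest window")
})
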