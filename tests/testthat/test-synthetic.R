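test_that("generators are bit-reproducible under a fixed seed", {
  sp <- simSpec(durationMs = 5000, miniRate = 1, noiseSigma = 2, seed = 33)
  a <- simulateQuantalRecording(sp)
  b <- simulateQuantalRecording(sp)
  expect_identical(signalValues(a$recording), signalValues(b$recording))
  expect_identical(a$truth, b$truth)

  proto <- protocolFromBlocks("1Hz", 1, 5, 500)
  spE <- simSpec(durationMs = 6000, noiseSigma = 1,
                 reference = list(baselineF = 50, noiseSigma = 0.5), seed = 4)
  e1 <- simulateEvokedRecording(spE, proto, gains = rep(1, 5))
  e2 <- simulateEvokedRecording(spE, proto, gains = rep(1, 5))
  expect_identical(signalValues(e1$recording), signalValues(e2$recording))
  expect_identical(referenceValues(e1$recording), referenceValues(e2$recording))

  m1 <- simulateMatchedPairs(50, 0.7, 0.2, seed = 5)
  m2 <- simulateMatchedPairs(50, 0.7, 0.2, seed = 5)
  expect_identical(m1, m2)
  expect_identical(azAmplitudes(simulateAZMatrix(seed = 6)),
                   azAmplitudes(simulateAZMatrix(seed = 6)))
})

test_that("quantal event counts follow the Poisson rate", {
  counts <- vapply(1:300, function(s) {
    nrow(simulateQuantalRecording(simSpec(durationMs = 60000, miniRate = 0.5,
                                          noiseSigma = 0, seed = s))$truth)
  }, numeric(1))
  # mean count ~ Poisson(30); CI for the mean of 300 draws
  expect_lt(abs(mean(counts) - 30), 3 * sqrt(30 / 300))
  # zero rate: flat trace, empty truth
  z <- simulateQuantalRecording(simSpec(durationMs = 5000, miniRate = 0,
                                        noiseSigma = 0, bleach = 0.97, seed = 1))
  expect_equal(nrow(z$truth), 0)
  tp <- timePoints(z$recording)
  expect_equal(signalValues(z$recording),
               100 * 0.97^(tp / 5000), tolerance = 1e-12)
})

test_that("evoked recordings superpose unit-peak kernels at stimulus times", {
  proto <- protocolFromBlocks("sparse", 0.5, 5, 2000)
  sim <- simulateEvokedRecording(
    simSpec(durationMs = 12000, frameRate = 1000, baselineF = 100,
            amplitude = 0.4, tauRise = 5, tauDecay = 40, miniRate = 0,
            noiseSigma = 0, bleach = 1, seed = 1),
    proto, gains = rep(1, 5))
  tr <- restNormalize(sim$recording, 2000, restMs = 500)
  v <- traceValues(tr)
  tp <- timePoints(tr)
  for (s in stimulusTimes(proto)) {
    expect_equal(max(v[tp >= s & tp < s + 2000]), 0.4, tolerance = 0.002)
  }
  expect_error(simulateEvokedRecording(
    simSpec(seed = 1), proto, gains = rep(1, 4)), "gains")
})

test_that("a common-bleach reference channel cancels in dR/R", {
  proto <- protocolFromBlocks("one", 1, 1, 2500)
  spec <- simSpec(durationMs = 5000, frameRate = 1000, baselineF = 100,
                  amplitude = 0.4, tauRise = 14, tauDecay = 67, miniRate = 0,
                  noiseSigma = 0, bleach = 0.9,
                  reference = list(baselineF = 50, noiseSigma = 0,
                                   bleach = 0.9),
                  seed = 2)
  sim <- simulateEvokedRecording(spec, proto, gains = 1)
  drr <- normalizeDRR(sim$recording)
  expect_equal(max(traceValues(drr)), 0.4, tolerance = 0.4 * 0.02)
})

test_that("matched-pair streams express rho and dropout", {
  mp <- simulateMatchedPairs(400, 1, dropout = 0, seed = 7)
  expect_equal(nrow(mp$optical), 400)
  mr <- matchEvents(mp$optical, mp$ephys, tolerance = 50)
  expect_equal(cor(matchedPairs(mr)$ephys_amplitude,
                   matchedPairs(mr)$optical_amplitude,
                   method = "spearman"), 1)
  # dropout thins optical events binomially
  kept <- vapply(1:100, function(s) {
    nrow(simulateMatchedPairs(200, 0.5, dropout = 0.4, seed = s)$optical)
  }, numeric(1))
  expect_lt(abs(mean(kept) / 200 - 0.6), 3 * sqrt(0.6 * 0.4 / (200 * 100)))
  expect_error(simulateMatchedPairs(10, 1.2, 0, seed = 1), "rho")
  expect_error(simulateMatchedPairs(10, 0.5, 1, seed = 1), "dropout")
})

test_that("AZ matrices have the requested design", {
  azm <- simulateAZMatrix(seed = 10)
  expect_equal(dim(azAmplitudes(azm)), c(30, 15))
  azm2 <- simulateAZMatrix(4, 6, azMeans = c(1, 2, 3, 4), sigma = 0,
                           seed = 1)
  expect_equal(rowMeans(azAmplitudes(azm2)), setNames(1:4, paste0("AZ", 1:4)),
               tolerance = 1e-12)
  expect_error(simulateAZMatrix(3, 5, azMeans = 1:2, seed = 1), "length")
})

test_that("simulations round-trip through the shared table format", {
  spec <- simSpec(durationMs = 4000, miniRate = 1, noiseSigma = 1,
                  reference = list(baselineF = 40, noiseSigma = 0.3), seed = 12)
  sim <- simulateQuantalRecording(spec)
  prefix <- tempfile()
  paths <- writeSimulation(sim, prefix)
  recs <- readTraceTable(paths[["signal"]])
  recs <- attachReference(recs, paths[["reference"]])
  expect_identical(signalValues(recs$sim), signalValues(sim$recording))
  expect_identical(referenceValues(recs$sim), referenceValues(sim$recording))
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$time, sim$truth$time)
})

test_that("invalid simulation specs are rejected", {
  expect_error(simSpec(durationMs = -1), "durationMs")
  expect_error(simSpec(bleach = 0), "bleach")
  expect_error(simSpec(bleach = 2), "bleach")
  expect_error(simSpec(tauRise = 0), "tauRise")
})
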