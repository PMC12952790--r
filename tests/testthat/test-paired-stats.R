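test_that("event matching pairs nearest events within tolerance", {
  eph <- data.frame(time = c(100, 200), amplitude = c(1, 1))
  opt <- data.frame(time = c(105, 500), amplitude = c(0.3, 0.3))
  mr <- matchEvents(opt, eph, tolerance = 50)
  expect_equal(nrow(matchedPairs(mr)), 1)
  expect_equal(matchedPairs(mr)$ephys_time, 100)
  expect_equal(matchedPairs(mr)$optical_time, 105)
  expect_equal(unmatchedEphys(mr)$time, 200)
  expect_equal(unmatchedOptical(mr)$time, 500)

  # globally nearest: 100 pairs with 90 (|dt| 10), not 140 (|dt| 40)
  mr2 <- matchEvents(data.frame(time = c(90, 140), amplitude = c(1, 1)),
                     data.frame(time = 100, amplitude = 1), tolerance = 50)
  expect_equal(matchedPairs(mr2)$optical_time, 90)
})

test_that("matching conserves counts and ignores input order", {
  set.seed(31)
  for (rep in 1:25) {
    ne <- sample(0:10, 1); no <- sample(0:10, 1)
    eph <- data.frame(time = sort(runif(ne, 0, 2000)),
                      amplitude = runif(ne, 0.2, 1))
    opt <- data.frame(time = sort(runif(no, 0, 2000)),
                      amplitude = runif(no, 0.1, 0.6))
    mr <- matchEvents(opt, eph, tolerance = 100)
    expect_equal(nrow(matchedPairs(mr)) + nrow(unmatchedEphys(mr)), ne)
    expect_equal(nrow(matchedPairs(mr)) + nrow(unmatchedOptical(mr)), no)
    # shuffled inputs give the identical pairing
    mrS <- matchEvents(opt[sample(no), , drop = FALSE],
                       eph[sample(ne), , drop = FALSE], tolerance = 100)
    expect_equal(matchedPairs(mrS), matchedPairs(mr))
    # agrees with an independent greedy-nearest oracle
    oracle <- bruteMatch(eph$time, opt$time, 100)
    expect_equal(nrow(matchedPairs(mr)), length(oracle))
    if (length(oracle)) {
      oeph <- sort(vapply(oracle, function(p) eph$time[p$i], numeric(1)))
      expect_equal(sort(matchedPairs(mr)$ephys_time), oeph)
    }
  }
})

test_that("detection fraction is pairs over total ephys events", {
  eph <- data.frame(time = seq(100, 1000, by = 100), amplitude = 1)
  opt <- data.frame(time = seq(100, 900, by = 100) + 5, amplitude = 0.3)
  mr <- matchEvents(opt, eph, tolerance = 50)
  expect_equal(detectionFraction(mr), 0.9)
  expect_equal(detectionFraction(matchEvents(eph, eph, tolerance = 1)), 1)
  none <- matchEvents(data.frame(time = numeric(0), amplitude = numeric(0)),
                      eph, tolerance = 50)
  expect_equal(detectionFraction(none), 0)
  empty <- matchEvents(opt, data.frame(time = numeric(0),
                                       amplitude = numeric(0)))
  expect_error(detectionFraction(empty), "no ephys")
})

test_that("amplitude correlation reports Pearson r, r^2 and n", {
  eph <- data.frame(time = seq(100, 1000, by = 100),
                    amplitude = c(0.3, 0.5, 0.7, 0.4, 0.9, 0.6, 0.8, 0.2, 1, 0.55))
  opt <- eph
  opt$amplitude <- 2 * eph$amplitude
  ac <- amplitudeCorrelation(matchEvents(opt, eph, tolerance = 10))
  expect_equal(ac$r, 1, tolerance = 1e-12)
  expect_equal(ac$n, 10)
  opt$amplitude <- -eph$amplitude + 3
  ac2 <- amplitudeCorrelation(matchEvents(opt, eph, tolerance = 10))
  expect_equal(ac2$r, -1, tolerance = 1e-12)
  opt$amplitude <- rep(0.4, 10)
  expect_error(amplitudeCorrelation(matchEvents(opt, eph, tolerance = 10)),
               "zero variance")
})

test_that("pairwise AZ tests equal stats::t.test on every pair", {
  azm <- simulateAZMatrix(6, 9, azMeans = seq(0.2, 0.45, length.out = 6),
                          sigma = 0.05, seed = 8)
  pw <- azPairwiseTests(azm)
  a <- azAmplitudes(azm)
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(pw$p_matrix[i, j],
                 t.test(a[i, ], a[j, ], paired = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  expect_equal(pw$n_pairs, choose(6, 2))
})

test_that("pairwise AZ tests separate shifted AZs and exclude degenerate pairs", {
  set.seed(9)
  base <- rnorm(15, 0.3, 0.02)
  m <- rbind(base, base + 0.5 + rnorm(15, 0, 0.01))
  pw <- azPairwiseTests(azMatrix(m))
  expect_lt(pw$p_matrix[1, 2], 1e-6)
  expect_equal(pw$fraction_significant, 1)
  # identical rows: difference variance zero -> excluded
  m2 <- rbind(base, base, base + 0.5 + rnorm(15, 0, 0.01))
  pw2 <- azPairwiseTests(azMatrix(m2))
  expect_equal(pw2$n_excluded, 1)
  expect_equal(pw2$n_pairs, 2)
  expect_error(azPairwiseTests(azMatrix(m[1, , drop = FALSE])), ">= 2 active")
})

test_that("IQR flagging uses linear-interpolation quartiles on pooled data", {
  azm <- azMatrix(matrix(1:100, nrow = 10, byrow = TRUE))
  fl <- iqrFlags(azm)
  expect_equal(fl$q1, 25.75)
  expect_equal(fl$q3, 75.25)
  # rows 1..10 have means 5.5, 15.5, ..., 95.5; flagged below Q1 / above Q3
  expect_setequal(fl$flagged, paste0("AZ", c(1, 2, 3, 8, 9, 10)))
  # all means at the pooled median: nothing flagged
  m <- matrix(rep(c(1, 3), 10), nrow = 5, byrow = TRUE)
  expect_length(iqrFlags(azMatrix(m))$flagged, 0)
})

test_that("KS comparisons enumerate the ECDF supremum", {
  expect_equal(ksCompare(1:20, 1:20)$D, 0)
  expect_equal(ksCompare(1:5, 101:105)$D, 1)
  expect_equal(ksCompare(c(1, 2, 3), c(2, 3, 4))$D, 1 / 3, tolerance = 1e-12)
  expect_error(ksCompare(numeric(0), 1:3), "non-empty")
})
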