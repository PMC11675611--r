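test_that("reference values follow the truncated normal contract", {
  y <- generateReferenceValues(92, 9.79, 0.7, 8.43, 11.25, seed = 1)
  expect_length(y, 92)
  expect_true(all(y >= 8.43 & y <= 11.25))
  expect_identical(y, generateReferenceValues(92, 9.79, 0.7, 8.43, 11.25,
                                              seed = 1))

  # degenerate-spread limit collapses onto the mean
  y0 <- generateReferenceValues(5, 9.79, 1e-12, 8.43, 11.25, seed = 2)
  expect_equal(y0, rep(9.79, 5), tolerance = 1e-8)

  # Monte-Carlo agreement with the stated distribution
  yl <- generateReferenceValues(1000, 9.79, 0.7, 8.43, 11.25, seed = 7)
  expect_lt(abs(mean(yl) - 9.79), 3 * 0.7 / sqrt(1000))

  expect_error(generateReferenceValues(10, lo = 11, hi = 9), "invalid range")
})

test_that("truncation never leaks outside the bounds", {
  for (s in 1:20) {
    y <- generateReferenceValues(200, 10, 2, 8.43, 11.25, seed = s)
    expect_true(all(y >= 8.43 & y <= 11.25))
  }
})

test_that("generated spectra have the study's dimensions and are seeded", {
  cfg <- syntheticConfig(seed = 5)
  d <- generateSpectra(cfg, generateReferenceValues(92, seed = 5))
  expect_identical(dim(intensityMatrix(d$spectra)), c(276L, 128L))
  expect_identical(length(unique(sampleIds(d$spectra))), 92L)
  expect_equal(range(wavelengths(d$spectra)), c(940, 1660))

  d2 <- generateSpectra(cfg, generateReferenceValues(92, seed = 5))
  expect_identical(intensityMatrix(d$spectra), intensityMatrix(d2$spectra))
  cfg2 <- syntheticConfig(seed = 6)
  d3 <- generateSpectra(cfg2, generateReferenceValues(92, seed = 5))
  expect_false(identical(intensityMatrix(d$spectra),
                         intensityMatrix(d3$spectra)))

  expect_error(generateSpectra(cfg, 1:5), "must equal nSamples")
})

test_that("a noiseless single-band spectrum is an exact linear map of protein", {
  cfg <- syntheticConfig(nSamples = 30, nReplicates = 1, seed = 3,
                         proteinBandCenters = 994, proteinBandWidths = 30,
                         proteinBandStrengths = 0.02,
                         interferentBandCenters = numeric(),
                         interferentBandWidths = numeric(),
                         interferentBandStrengths = numeric(),
                         scatterSlopeSd = 0, scatterOffsetSd = 0,
                         driftAmplitude = 0, noiseSd = 0)
  ref <- generateReferenceValues(30, seed = 3)
  d <- generateSpectra(cfg, ref)
  wl <- wavelengths(d$spectra)
  ch <- which.min(abs(wl - 994))
  expect_equal(cor(intensityMatrix(d$spectra)[, ch], ref), 1,
               tolerance = 1e-12)
})

test_that("without scatter and noise, PLSR with one LV per constituent is exact", {
  cfg <- syntheticConfig(nSamples = 20, nReplicates = 1, seed = 4,
                         scatterSlopeSd = 0, scatterOffsetSd = 0,
                         noiseSd = 0)
  ref <- generateReferenceValues(20, seed = 4)
  d <- generateSpectra(cfg, ref)
  X <- intensityMatrix(d$spectra)
  # varying directions: protein + 4 interferent concentrations + drift slope
  nConstituents <- 1 + length(cfg@interferentBandCenters) + 1
  m <- plsrFit(X, ref, nConstituents)
  expect_lt(sqrt(mean((ref - predict(m, X))^2)), 1e-8)
})

test_that("multiplicative scatter slopes are recovered at the configured SD", {
  cfg <- syntheticConfig(nSamples = 500, nReplicates = 1, seed = 11,
                         scatterSlopeSd = 0.1, scatterOffsetSd = 0,
                         driftAmplitude = 0, noiseSd = 1e-4)
  d <- generateSpectra(cfg, generateReferenceValues(500, seed = 11))
  X <- intensityMatrix(d$spectra)
  m <- colMeans(X)
  mc <- m - mean(m)
  slopes <- as.vector(X %*% mc) / sum(mc^2)
  expect_lt(abs(sd(slopes) - 0.1), 0.025)
})

test_that("configuration invariants are enforced", {
  expect_error(syntheticConfig(wlMin = 1700), "wlMin")
  expect_error(syntheticConfig(proteinMin = 10, proteinMean = 9), "proteinMin")
  expect_error(syntheticConfig(noiseSd = -1), "SDs")
  expect_error(syntheticConfig(proteinBandCenters = 500,
                               proteinBandWidths = 10,
                               proteinBandStrengths = 0.01), "band centers")
})
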