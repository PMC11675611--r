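test_that("SG smoothing fixes polynomials up to the fit order", {
  ramp <- matrix(0:6, 1)
  expect_equal(sgSmooth(ramp, 5, 2), ramp, tolerance = 1e-10)
  quad <- matrix((0:6)^2, 1)
  expect_equal(sgSmooth(quad, 5, 2), quad, tolerance = 1e-10)
  expect_error(sgSmooth(ramp, 4, 2), "odd")
  expect_error(sgSmooth(ramp, 5, 5), "polyorder")
})

test_that("SG smoothing is linear and reduces white-noise variance", {
  set.seed(10)
  x <- matrix(rnorm(128), 1)
  z <- matrix(rnorm(128), 1)
  expect_equal(sgSmooth(2 * x + 3 * z, 5, 2),
               2 * sgSmooth(x, 5, 2) + 3 * sgSmooth(z, 5, 2),
               tolerance = 1e-10)

  N <- matrix(rnorm(1000 * 128), 1000, 128) + 7
  S <- sgSmooth(N, 5, 2)
  expect_lt(mean(apply(S, 2, var)), mean(apply(N, 2, var)))
})

test_that("MSC recovers affine-distorted spectra against the reference", {
  ref <- rbind(c(1, 2, 3), c(1, 2, 3))
  m <- mscFit(ref)
  # a row equal to the reference is returned unchanged
  expect_equal(mscApply(m, rbind(c(1, 2, 3))), rbind(c(1, 2, 3)))
  # exact algebra: [5,7,9] = 3 + 2 * [1,2,3]
  expect_equal(mscApply(m, rbind(c(5, 7, 9))), rbind(c(1, 2, 3)))
  expect_error(mscFit(rbind(c(1, 1, 1), c(1, 1, 1))), "degenerate reference")
  expect_error(mscApply(m, rbind(c(2, 2, 2))), "degenerate sample")
})

test_that("post-MSC spectra refit to slope 1 and intercept 0", {
  cfg <- syntheticConfig(nSamples = 40, nReplicates = 1, seed = 8,
                         scatterSlopeSd = 0.1, scatterOffsetSd = 0.05,
                         driftAmplitude = 0, noiseSd = 0)
  d <- generateSpectra(cfg, generateReferenceValues(40, seed = 8))
  X <- intensityMatrix(d$spectra)
  m <- mscFit(X)
  Xc <- mscApply(m, X)
  ref <- m@referenceMean
  refC <- ref - mean(ref)
  slopes <- as.vector(Xc %*% refC) / sum(refC^2)
  intercepts <- rowMeans(Xc) - slopes * mean(ref)
  expect_equal(unname(slopes), rep(1, 40), tolerance = 1e-8)
  expect_equal(unname(intercepts), rep(0, 40), tolerance = 1e-8)
})

test_that("SNV standardizes each spectrum and ignores affine distortion", {
  expect_equal(snv(rbind(c(1, 2, 3))), rbind(c(-1, 0, 1)))
  set.seed(3)
  X <- matrix(rnorm(5 * 20), 5, 20)
  S <- snv(X)
  expect_equal(unname(rowMeans(S)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(S, 1, sd)), rep(1, 5), tolerance = 1e-12)
  expect_equal(snv(3 + 2 * X), snv(X), tolerance = 1e-12)
  expect_error(snv(rbind(rep(1, 4))), "zero-variance spectrum in row 1")
})

test_that("first derivative matches hand-computed differences", {
  wl <- 1:5
  expect_equal(firstDerivative(rbind(rep(4, 5)), wl), rbind(rep(0, 5)))
  expect_equal(firstDerivative(matrix(wl, 1), wl), matrix(1, 1, 5))
  expect_equal(firstDerivative(rbind(c(0, 1, 4, 9, 16)), wl),
               rbind(c(1, 2, 4, 6, 7)))
  expect_error(firstDerivative(rbind(c(1, 2)), 1:2), "3 channels")
})

test_that("derivative of smoothed quadratics equals the analytic derivative", {
  wl <- seq(940, 1660, length.out = 64)
  X <- rbind(2 + 0.003 * wl + 1e-6 * wl^2)
  d <- firstDerivative(sgSmooth(X, 5, 2), wl)
  expect_equal(d[1, 2:63], 0.003 + 2e-6 * wl[2:63], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("combined variants derive first, then apply the second step", {
  wl <- seq(940, 1660, length.out = 32)
  set.seed(5)
  base <- matrix(rnorm(6), 6, 1) %*% rep(1, 32)       # per-spectrum baseline
  ramp <- outer(runif(6, 0.5, 1.5), wl / 1000)
  X <- base + ramp + outer(rep(1, 6), sin(wl / 50))
  out <- applyPreprocessing("1D+SNV", X[1:4, ], X[5:6, ], wl)
  expect_equal(unname(rowMeans(out$calibration)), rep(0, 4),
               tolerance = 1e-12)
  expect_equal(unname(rowMeans(out$prediction)), rep(0, 2),
               tolerance = 1e-12)

  idn <- applyPreprocessing("X", X[1:4, ], X[5:6, ], wl)
  expect_identical(idn$calibration, X[1:4, ])
  expect_identical(idn$prediction, X[5:6, ])
  expect_error(applyPreprocessing("bogus", X[1:4, ], NULL, wl), "unknown")
})

test_that("calibration-fitted MSC transfers to prediction spectra", {
  cfg <- syntheticConfig(seed = 9)
  data <- preparedData(cfg)
  out <- applyPreprocessing("1D+MSC", data$XCal, data$XPred,
                            data$wavelengths)
  dCal <- firstDerivative(data$XCal, data$wavelengths)
  ref <- colMeans(dCal)                 # MSC reference = calibration mean
  refC <- ref - mean(ref)
  slopes <- as.vector(out$prediction %*% refC) / sum(refC^2)
  expect_true(all(abs(slopes - 1) < 0.05))
})

test_that("preprocessing never uses prediction rows to fit statistics", {
  cfg <- syntheticConfig(seed = 12)
  data <- preparedData(cfg)
  perm <- sample(nrow(data$XPred))
  for (name in c("X", "SG", "MSC", "SNV", "1D", "1D+SG", "1D+MSC", "1D+SNV")) {
    a <- applyPreprocessing(name, data$XCal, data$XPred, data$wavelengths)
    b <- applyPreprocessing(name, data$XCal, data$XPred[perm, ],
                            data$wavelengths)
    expect_identical(a$calibration, b$calibration)
    expect_equal(unname(a$prediction[perm, ]), unname(b$prediction),
                 tolerance = 1e-12)
  }
})
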