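test_that("the SPA projection chain follows the hand-worked example", {
  X <- cbind(c(1, 0, 0), c(0.8, 0.6, 0), c(0, 0, 1))
  # from x1: x3's residual norm (1) beats x2's (0.6) after removing x1
  expect_identical(NIRcal:::spaChain(X, 1L, 3L), c(1L, 3L, 2L))
})

test_that("SPA chains match the from-scratch QR projection oracle", {
  for (s in 1:5) {
    set.seed(s)
    X <- matrix(rnorm(20 * 8), 20, 8)
    for (start in 1:8)
      expect_identical(NIRcal:::spaChain(X, start, 8L),
                       NIRcal:::spaChainBruteForce(X, start, 8L))
  }
})

test_that("duplicated columns never both enter a chain", {
  set.seed(20)
  X <- matrix(rnorm(20 * 6), 20, 6)
  X[, 5] <- X[, 2]
  for (start in 1:6) {
    chain <- NIRcal:::spaChain(X, start, 6L)
    expect_lte(sum(chain %in% c(2L, 5L)), 1L)
  }
})

test_that("SPA residual norms are non-increasing and selections independent", {
  set.seed(21)
  X <- matrix(rnorm(25 * 10), 25, 10)
  chain <- NIRcal:::spaChain(X, 3L, 8L)
  norms <- sapply(seq_along(chain), function(k) {
    if (k == 1) return(sum(X[, chain[1]]^2))
    Q <- qr.Q(qr(X[, chain[seq_len(k - 1)], drop = FALSE]))
    v <- X[, chain[k]]
    sum((v - Q %*% crossprod(Q, v))^2)
  })
  expect_true(all(diff(norms) < 1e-10))
  expect_equal(qr(X[, chain, drop = FALSE])$rank, length(chain))
})

test_that("spaSelect returns the CV-minimizing prefix of the winning chain", {
  set.seed(22)
  S <- matrix(rnorm(40 * 3), 40, 3)
  X <- cbind(S, S %*% matrix(rnorm(9), 3, 3) + matrix(rnorm(120, 0, 0.05),
                                                      40, 3))
  y <- as.vector(S %*% c(1, -2, 1)) + rnorm(40, 0, 0.01)
  res <- spaSelect(X, y, maxVars = 5, seed = 1, wavelengths = seq(940, by = 10,
                                                                  length.out = 6))
  idx <- selectedIndices(res)
  expect_true(length(idx) >= 1 && length(idx) <= 5)
  sizes <- res@chainBySize
  best <- which.min(vapply(sizes, `[[`, numeric(1), "cvRmse"))
  expect_identical(idx, as.integer(sizes[[best]]$indices))
  expect_identical(selectedWavelengths(res),
                   seq(940, by = 10, length.out = 6)[idx])
  expect_identical(res, spaSelect(X, y, maxVars = 5, seed = 1,
                                  wavelengths = seq(940, by = 10,
                                                    length.out = 6)))
  expect_error(spaSelect(X, y, maxVars = 50), "maxVars")
})

test_that("UVE augments with one noise variable per real channel", {
  set.seed(23)
  X <- matrix(rnorm(25 * 128), 25, 128)
  y <- X[, 10] + rnorm(25, 0, 0.1)
  res <- uveSelect(X, y, nLv = 3, seed = 1)
  expect_length(stabilityProfile(res), 256L)
  idx <- selectedIndices(res)
  expect_true(all(idx >= 1 & idx <= 128))   # never an artificial column
  expect_gt(hMax(res), 0)
  expect_true(all(abs(stabilityProfile(res)[idx]) > hMax(res)))
  expect_identical(res, uveSelect(X, y, nLv = 3, seed = 1))
})

test_that("UVE recovers a known contiguous support and rejects the rest", {
  sup <- trueSupportChannels(knownSupportConfig(1), 0.05)
  expect_identical(sup, 41:51)
  stats <- sapply(1:20, function(s) {
    cfg <- knownSupportConfig(s)
    d <- generateDataset(cfg)
    avg <- averageReplicates(d$spectra)
    xy <- joinReference(avg, d$reference)
    part <- concentrationGradientSplit(xy$y)
    Xc <- xy$X[calibrationIndices(part), ]
    yc <- xy$y[calibrationIndices(part)]
    nLv <- selectNComponents(Xc, yc, 10, 5, s)
    sel <- selectedIndices(uveSelect(Xc, yc, nLv, seed = s))
    c(supportKept = mean(sup %in% sel),
      othersRemoved = 1 - length(setdiff(sel, sup)) / (128 - length(sup)))
  })
  expect_identical(median(stats["supportKept", ]), 1)
  expect_gte(median(stats["othersRemoved", ]), 0.95)
})

test_that("an exact copy of a pure-noise column is eliminated", {
  hits <- sapply(1:20, function(s) {
    set.seed(s)
    S <- matrix(rnorm(40 * 2), 40, 2)
    X <- cbind(S %*% matrix(rnorm(2 * 9), 2, 9) +
                 matrix(rnorm(360, 0, 0.02), 40, 9),
               rnorm(40))                    # column 10 is pure noise
    y <- as.vector(S %*% c(1, -1)) + rnorm(40, 0, 0.02)
    10L %in% selectedIndices(uveSelect(X, y, nLv = 2, seed = s))
  })
  expect_lte(mean(hits), 0.05)
})
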