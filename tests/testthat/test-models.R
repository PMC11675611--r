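test_that("PLSR fits a rank-1 response exactly with one component", {
  set.seed(1)
  x <- rnorm(20)
  X <- cbind(x, matrix(0, 20, 3))
  y <- 2 * x
  m <- plsrFit(X, y, 1)
  expect_lt(max(abs(predict(m, X) - y)), 1e-10)
  expect_error(plsrFit(X, rep(1, 20), 1), "constant")
})

test_that("full-rank PLSR equals the OLS normal-equations solution", {
  set.seed(2)
  X <- matrix(rnorm(100), 20, 5)
  y <- rnorm(20)
  m <- plsrFit(X, y, 5)
  Xc <- scale(X, scale = FALSE)
  bOls <- solve(crossprod(Xc), crossprod(Xc, y - mean(y)))
  expect_lt(max(abs(m@coefficients - bOls)), 1e-8)
})

test_that("PLSR scores are orthogonal and predictions are permutation-invariant", {
  set.seed(3)
  X <- matrix(rnorm(30 * 10), 30, 10)
  y <- X %*% rnorm(10) + rnorm(30, 0, 0.1)
  m <- plsrFit(X, y[, 1], 4)
  G <- crossprod(m@scores)
  expect_lt(max(abs(G[upper.tri(G)])) / max(diag(G)), 1e-10)

  perm <- sample(10)
  m2 <- plsrFit(X[, perm], y[, 1], 4)
  expect_equal(predict(m2, X[, perm]), predict(m, X), tolerance = 1e-8)
})

test_that("component selection finds low-rank structure deterministically", {
  set.seed(4)
  S <- matrix(rnorm(40 * 3), 40, 3)
  X <- S %*% matrix(rnorm(3 * 12), 3, 12)
  y <- S %*% c(1, -1, 0.5)
  k <- selectNComponents(X, y[, 1], maxComponents = 8, seed = 1)
  expect_lte(k, 3L)
  expect_lt(attr(k, "cvRmse")[k], 1e-6)
  expect_identical(k, selectNComponents(X, y[, 1], maxComponents = 8,
                                        seed = 1))

  yn <- rnorm(40)
  expect_lte(selectNComponents(X, yn, maxComponents = 8, seed = 1), 8L)
})

test_that("linear SVR recovers an exactly linear map", {
  set.seed(5)
  X <- matrix(rnorm(200), 40, 5)
  y <- as.vector(X %*% c(1, -2, 0.5, 0, 3)) + 2
  m <- svrFit(X, y, "linear", cost = 1e4, epsilon = 1e-4)
  expect_lt(sqrt(mean((y - predict(m, X))^2)), 1e-3)
  expect_error(svrFit(X, y, "linear", cost = -1), "cost")
  expect_error(svrFit(X, y, "rbf", cost = 1, gamma = 0), "gamma")
})

test_that("RBF SVR flattens toward the response mean as g tends to 0", {
  set.seed(6)
  X <- matrix(runif(60), 20, 3)
  y <- sin(3 * X[, 1]) - mean(sin(3 * X[, 1]))
  m <- svrFit(X, y, "rbf", cost = 10, gamma = 1e-9, epsilon = 0.01)
  p <- predict(m, X)
  expect_lt(sd(p), 1e-6 * sd(y))
  expect_lt(max(abs(p - mean(y))), 0.3 * sd(y))
})

test_that("SVR is stable under duplicated training points", {
  set.seed(7)
  X <- matrix(rnorm(100), 20, 5)
  y <- as.vector(X %*% rnorm(5))
  m1 <- svrFit(X, y, "linear", cost = 10, epsilon = 0.01)
  m2 <- svrFit(rbind(X, X[1, ]), c(y, y[1]), "linear", cost = 10,
               epsilon = 0.01)
  expect_lt(max(abs(predict(m1, X) - predict(m2, X))), 1e-6)
})

test_that("the SVR tuning grid is half-integer powers of two", {
  g <- round(svrParameterGrid(), 4)
  expect_true(all(c(724.0773, 2.8284, 0.0442, 90.5097, 11.3137, 0.0625)
                  %in% g))
  expect_length(svrParameterGrid(), 41L)
})

test_that("grid search honors the kernel and reports no gamma for linear", {
  set.seed(8)
  X <- matrix(rnorm(150), 30, 5)
  y <- as.vector(X %*% c(2, -1, 0, 0.5, 1))
  gl <- svrGridSearch(X, y, "linear", kFolds = 3, seed = 1)
  expect_true(is.na(gl$gamma))
  expect_true(gl$cost %in% svrParameterGrid())
  # on exactly linear noiseless data the linear kernel cannot lose to rbf
  gr <- svrGridSearch(X, y, "rbf", kFolds = 3, seed = 1)
  expect_lte(gl$cvRmse, gr$cvRmse)
})

test_that("ELM interpolates with as many neurons as training points", {
  set.seed(9)
  X <- matrix(runif(60), 20, 3)
  y <- sin(3 * X[, 1]) + X[, 2]^2
  m <- elmFit(X, y, 20, seed = 1)
  expect_lt(sqrt(mean((y - predict(m, X))^2)), 1e-4)

  mc <- elmFit(X, rep(2.5, 20), 20, seed = 1)
  expect_lt(max(abs(predict(mc, X) - 2.5)), 1e-6)
  expect_error(elmFit(X, y, 0), "nNeurons")
})

test_that("ELM is deterministic given its seed and varies across seeds", {
  set.seed(10)
  X <- matrix(runif(60), 20, 3)
  y <- X %*% c(1, 2, 3)
  p1 <- predict(elmFit(X, y[, 1], 10, seed = 5), X)
  p2 <- predict(elmFit(X, y[, 1], 10, seed = 5), X)
  p3 <- predict(elmFit(X, y[, 1], 10, seed = 6), X)
  expect_identical(p1, p2)
  expect_false(identical(p1, p3))
})

test_that("ELM training error decreases with network size in the median", {
  set.seed(11)
  X <- matrix(runif(120), 40, 3)
  y <- sin(3 * X[, 1]) + cos(2 * X[, 2])
  trainRmse <- function(L, s) {
    m <- elmFit(X, y, L, seed = s)
    sqrt(mean((y - predict(m, X))^2))
  }
  med <- sapply(c(5, 15, 35), function(L)
    median(sapply(1:20, function(s) trainRmse(L, s))))
  expect_true(all(diff(med) < 0))
})

test_that("neuron-count selection is deterministic and near-optimal", {
  set.seed(12)
  X <- matrix(runif(150), 50, 3)
  y <- as.vector(X %*% c(1, -2, 0.5))
  k <- selectNNeurons(X, y, candidates = seq(10, 40, 5), seed = 2)
  expect_identical(k, selectNNeurons(X, y, candidates = seq(10, 40, 5),
                                     seed = 2))
  curve <- attr(k, "cvRmse")
  expect_lte(curve[as.character(k)], 1.1 * min(curve))
  expect_error(selectNNeurons(X, y, candidates = c(0, 10)), "\\[1, 200\\]")
})
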