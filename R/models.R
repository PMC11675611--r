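#' Fit a PLS regression model by NIPALS
#'
#' Univariate-y NIPALS: X is column-centered and y centered; each component
#' takes the weight vector proportional to X'y, scores t = Xw, X/y are
#' deflated by the loading p = X't / t't and q = y't / t't. Regression
#' coefficients are W (P'W)^-1 q. Extraction stops early (with a warning) if
#' the residual X becomes numerically rank-deficient.
#'
#' @param X matrix, samples x channels.
#' @param y numeric response (protein content, % mass); must not be constant.
#' @param nComponents number of latent variables,
#'   `1 <= nComponents <= min(nrow - 1, ncol)`.
#' @return A [PLSRModel].
#' @examples
#' X <- matrix(rnorm(100), 20, 5)
#' y <- X[, 1] - 2 * X[, 3] + rnorm(20, 0, 0.1)
#' m <- plsrFit(X, y, 3)
#' predict(m, X)[1:3]
#' @export
plsrFit <- function(X, y, nComponents) {
  X <- assertMatrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (stats::sd(y) == 0) stop("degenerate target: y is constant")
  a <- as.integer(nComponents)
  if (a < 1L || a > min(n - 1L, p))
    stop("nComponents must be in [1, min(nrow - 1, ncol)]")
  xMean <- colMeans(X)
  E <- sweep(X, 2L, xMean)
  yMean <- mean(y)
  f <- y - yMean
  W <- matrix(0, p, a); P <- matrix(0, p, a); Tm <- matrix(0, n, a)
  q <- numeric(a)
  for (k in seq_len(a)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      a <- k - 1L
      warning("residual X'y vanished; keeping ", a, " components")
      break
    }
    w <- w / nw
    t <- as.vector(E %*% w)
    tt <- sum(t^2)
    if (tt < 1e-12) {
      a <- k - 1L
      warning("degenerate score vector; keeping ", a, " components")
      break
    }
    pv <- as.vector(crossprod(E, t)) / tt
    qk <- sum(f * t) / tt
    E <- E - tcrossprod(t, pv)
    f <- f - qk * t
    W[, k] <- w; P[, k] <- pv; Tm[, k] <- t; q[k] <- qk
  }
  if (a < 1L) stop("no usable latent variable could be extracted")
  W <- W[, seq_len(a), drop = FALSE]; P <- P[, seq_len(a), drop = FALSE]
  Tm <- Tm[, seq_len(a), drop = FALSE]; q <- q[seq_len(a)]
  B <- plsrCoefPath(W, P, q)
  new("PLSRModel", nComponents = a, weights = W, loadings = P,
      yLoadings = q, scores = Tm, xMean = xMean, yMean = yMean,
      coefficients = B[, a])
}

# p x A matrix whose k-th column is the coefficient vector using k components
# (centered scale). Uses the rotation R = W (P'W)^-1 built incrementally.
plsrCoefPath <- function(W, P, q) {
  p <- nrow(W); a <- ncol(W)
  R <- matrix(0, p, a)
  B <- matrix(0, p, a)
  bk <- numeric(p)
  for (k in seq_len(a)) {
    r <- W[, k]
    if (k > 1L) {
      prev <- seq_len(k - 1L)
      r <- r - R[, prev, drop = FALSE] %*% crossprod(P[, prev, drop = FALSE],
                                                     W[, k])
    }
    R[, k] <- r
    bk <- bk + q[k] * r
    B[, k] <- bk
  }
  B
}

#' @describeIn plsrFit Predict from a fitted PLSR model; `nComponents`
#'   (default: all fitted) allows prediction from a truncated component
#'   sequence.
#' @param object a [PLSRModel].
#' @param newdata matrix with the training channel count.
#' @param nComponents number of components to use for prediction.
#' @param ... ignored.
#' @export
setMethod("predict", "PLSRModel",
          function(object, newdata, nComponents = object@nComponents, ...) {
  newdata <- assertMatrix(newdata)
  if (ncol(newdata) != length(object@xMean))
    stop("channel count does not match the fitted model")
  k <- as.integer(nComponents)
  if (k < 1L || k > object@nComponents)
    stop("nComponents out of the fitted range")
  b <- if (k == object@nComponents) object@coefficients
       else plsrCoefPath(object@weights, object@loadings,
                         object@yLoadings)[, k]
  as.vector(sweep(newdata, 2L, object@xMean) %*% b) + object@yMean
})

#' Choose the number of PLSR latent variables by cross-validation
#'
#' k-fold CV RMSE is computed for every component count up to
#' `maxComponents` (capped by the fold training sizes); the minimizer is
#' returned, with ties broken toward fewer components. Deterministic given
#' `seed` (fold assignment).
#'
#' @param X,y training data.
#' @param maxComponents upper bound on the component count (default 20).
#' @param kFolds number of CV folds (default 5).
#' @param seed integer RNG seed for the fold assignment.
#' @return The selected component count (integer), with the CV RMSE curve
#'   attached as attribute `"cvRmse"`.
#' @export
selectNComponents <- function(X, y, maxComponents = 20L, kFolds = 5L,
                              seed = 1L) {
  X <- assertMatrix(X)
  n <- nrow(X)
  folds <- foldAssignments(n, kFolds, seed)
  minTrain <- n - max(table(folds))
  aMax <- min(as.integer(maxComponents), minTrain - 1L, ncol(X))
  if (aMax < 1L) stop("too few samples for cross-validation")
  sse <- numeric(aMax)
  for (f in sort(unique(folds))) {
    tr <- folds != f
    m <- plsrFit(X[tr, , drop = FALSE], y[tr], aMax)
    for (k in seq_len(m@nComponents)) {
      pred <- predict(m, X[!tr, , drop = FALSE], nComponents = k)
      sse[k] <- sse[k] + sum((y[!tr] - pred)^2)
    }
    if (m@nComponents < aMax)  # rank-deficient fold: reuse the last fit
      for (k in seq(m@nComponents + 1L, aMax))
        sse[k] <- sse[k] + sum((y[!tr] -
          predict(m, X[!tr, , drop = FALSE]))^2)
  }
  rmse <- sqrt(sse / n)
  best <- which.min(rmse)                   # first minimum = fewest components
  structure(as.integer(best), cvRmse = rmse)
}

# ---------------------------------------------------------------------------
# SVR
# ---------------------------------------------------------------------------

#' Fit an epsilon-support-vector regression model
#'
#' Standard dual-formulation epsilon-SVR (libsvm via e1071), with a linear
#' kernel K(xi, xj) = xi . xj or an RBF kernel
#' K(xi, xj) = exp(-g ||xi - xj||^2), g = 1 / (2 sigma^2). Features are used
#' as given (no internal rescaling).
#'
#' @param X,y training data.
#' @param kernel `"linear"` or `"rbf"`.
#' @param cost penalty parameter c (> 0).
#' @param gamma RBF parameter g (> 0); ignored for the linear kernel.
#' @param epsilon insensitive-tube half-width in y units (default 0.01).
#' @return An [SVRModel].
#' @export
svrFit <- function(X, y, kernel = c("linear", "rbf"), cost,
                   gamma = NA_real_, epsilon = 0.01) {
  kernel <- match.arg(kernel)
  X <- assertMatrix(X)
  if (!(is.finite(cost) && cost > 0)) stop("cost must be > 0")
  if (kernel == "rbf" && !(is.finite(gamma) && gamma > 0))
    stop("gamma must be > 0 for the rbf kernel")
  fit <- e1071::svm(x = X, y = as.numeric(y), type = "eps-regression",
                    kernel = if (kernel == "linear") "linear" else "radial",
                    cost = cost,
                    gamma = if (kernel == "rbf") gamma else 1 / ncol(X),
                    epsilon = epsilon, scale = FALSE)
  new("SVRModel", kernel = kernel, cost = cost,
      gamma = if (kernel == "rbf") gamma else NA_real_,
      epsilon = epsilon, fit = fit)
}

#' @describeIn svrFit Predict from a fitted SVR model.
#' @param object an [SVRModel].
#' @param newdata matrix with the training channel count.
#' @param ... ignored.
#' @export
setMethod("predict", "SVRModel", function(object, newdata, ...) {
  as.vector(stats::predict(object@fit, assertMatrix(newdata)))
})

#' The c/g candidate grid used for SVR tuning
#'
#' Half-integer powers of two, `2^e` for `e = -10, -9.5, ..., 10`; this grid
#' contains e.g. 2^9.5 = 724.0773, 2^1.5 = 2.8284 and 2^-4.5 = 0.0442 (to
#' four decimals).
#'
#' @return Numeric vector of 41 candidate values.
#' @export
svrParameterGrid <- function() 2^seq(-10, 10, by = 0.5)

#' Grid search for SVR tuning parameters
#'
#' Exhaustive search over the half-integer power-of-two grid
#' ([svrParameterGrid()]) minimizing k-fold CV RMSE; ties are broken toward
#' smaller c, then smaller g. The linear kernel searches c only and reports
#' `gamma = NA`.
#'
#' @param X,y training data (>= 2 * kFolds samples).
#' @param kernel `"linear"` or `"rbf"`.
#' @param kFolds number of CV folds (default 5).
#' @param seed fold-assignment seed.
#' @param epsilon tube half-width passed to [svrFit()].
#' @return List with `cost`, `gamma`, `cvRmse` and `model` (an [SVRModel]
#'   refitted on all of X, y).
#' @export
svrGridSearch <- function(X, y, kernel = c("linear", "rbf"), kFolds = 5L,
                          seed = 1L, epsilon = 0.01) {
  kernel <- match.arg(kernel)
  X <- assertMatrix(X)
  n <- nrow(X)
  if (n < 2L * kFolds) stop("need at least 2 * kFolds samples")
  folds <- foldAssignments(n, kFolds, seed)
  grid <- svrParameterGrid()
  gammas <- if (kernel == "rbf") grid else NA_real_
  best <- list(cost = NA_real_, gamma = NA_real_, cvRmse = Inf)
  for (cc in grid) {
    for (gg in gammas) {
      sse <- 0
      for (f in sort(unique(folds))) {
        tr <- folds != f
        m <- svrFit(X[tr, , drop = FALSE], y[tr], kernel, cost = cc,
                    gamma = gg, epsilon = epsilon)
        sse <- sse + sum((y[!tr] - predict(m, X[!tr, , drop = FALSE]))^2)
      }
      r <- sqrt(sse / n)
      if (r < best$cvRmse)                  # strict: first (smallest c, g) wins
        best <- list(cost = cc, gamma = gg, cvRmse = r)
    }
  }
  best$model <- svrFit(X, y, kernel, cost = best$cost, gamma = best$gamma,
                       epsilon = epsilon)
  best
}

# ---------------------------------------------------------------------------
# ELM
# ---------------------------------------------------------------------------

sigmoid <- function(z) 1 / (1 + exp(-z))

# Min-max scale columns to [-1, 1] using stored bounds; constant columns -> 0.
elmScale <- function(X, xMin, xMax) {
  rng <- xMax - xMin
  rng[rng == 0] <- 1
  sweep(sweep(X, 2L, (xMin + xMax) / 2), 2L, rng / 2, "/")
}

#' Fit an extreme learning machine regression model
#'
#' Inputs are min-max scaled to [-1, 1] (bounds from the training data);
#' input weights and hidden biases are drawn uniform(-1, 1) from `seed`; the
#' output weights solve the hidden-layer least-squares problem by
#' Moore-Penrose pseudoinverse.
#'
#' @param X,y training data.
#' @param nNeurons hidden-layer size (>= 1).
#' @param seed RNG seed for the random layer.
#' @return An [ELMModel].
#' @export
elmFit <- function(X, y, nNeurons, seed = 1L) {
  X <- assertMatrix(X)
  L <- as.integer(nNeurons)
  if (L < 1L) stop("nNeurons must be >= 1")
  p <- ncol(X)
  xMin <- apply(X, 2L, min); xMax <- apply(X, 2L, max)
  withSeed(seed, {
    Wt <- matrix(stats::runif(p * L, -1, 1), p, L)
    bias <- stats::runif(L, -1, 1)
  })
  H <- sigmoid(elmScale(X, xMin, xMax) %*% Wt +
               rep(bias, each = nrow(X)))
  beta <- as.vector(MASS::ginv(H) %*% as.numeric(y))
  new("ELMModel", nNeurons = L, inputWeights = Wt, biases = bias,
      outputWeights = beta, xMin = xMin, xMax = xMax,
      seed = as.integer(seed))
}

#' @describeIn elmFit Predict from a fitted ELM model.
#' @param object an [ELMModel].
#' @param newdata matrix with the training channel count.
#' @param ... ignored.
#' @export
setMethod("predict", "ELMModel", function(object, newdata, ...) {
  newdata <- assertMatrix(newdata)
  H <- sigmoid(elmScale(newdata, object@xMin, object@xMax) %*%
               object@inputWeights + rep(object@biases, each = nrow(newdata)))
  as.vector(H %*% object@outputWeights)
})

#' Choose the ELM hidden-layer size by cross-validation
#'
#' k-fold CV RMSE per candidate size, with the same random-layer seed reused
#' for every candidate so the comparison is deterministic; ties go to the
#' smallest network.
#'
#' @param X,y training data.
#' @param candidates candidate neuron counts (default 10:60, within
#'   [1, 200]).
#' @param kFolds number of CV folds (default 5).
#' @param seed seed for both the fold assignment and the random layers.
#' @return Selected neuron count (integer) with attribute `"cvRmse"`.
#' @export
selectNNeurons <- function(X, y, candidates = 10:60, kFolds = 5L, seed = 1L) {
  X <- assertMatrix(X)
  candidates <- sort(unique(as.integer(candidates)))
  if (any(candidates < 1L | candidates > 200L))
    stop("candidate neuron counts must lie in [1, 200]")
  folds <- foldAssignments(nrow(X), kFolds, seed)
  rmse <- vapply(candidates, function(L) {
    sse <- 0
    for (f in sort(unique(folds))) {
      tr <- folds != f
      m <- elmFit(X[tr, , drop = FALSE], y[tr], L, seed = seed)
      sse <- sse + sum((y[!tr] - predict(m, X[!tr, , drop = FALSE]))^2)
    }
    sqrt(sse / nrow(X))
  }, numeric(1))
  structure(candidates[which.min(rmse)],
            cvRmse = stats::setNames(rmse, candidates))
}
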