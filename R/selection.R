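# Multiple linear regression CV score for a candidate channel subset.
# Rank-deficient fits are handled by zeroing the aliased coefficients.
mlrCvSse <- function(X, y, idx, folds) {
  sse <- 0
  for (f in sort(unique(folds))) {
    tr <- folds != f
    A <- cbind(1, X[tr, idx, drop = FALSE])
    fit <- stats::lm.fit(A, y[tr])
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    pred <- cbind(1, X[!tr, idx, drop = FALSE]) %*% beta
    sse <- sse + sum((y[!tr] - pred)^2)
  }
  sse
}

#' Successive projections algorithm (SPA) wavelength selection
#'
#' For every starting channel a projection chain is grown: at each step all
#' candidate columns are projected onto the orthogonal complement of the
#' span of the already-selected columns, and the column with the largest
#' residual norm enters next (so selected channels are minimally collinear).
#' Every (start, subset size) prefix is scored by multiple-linear-regression
#' RMSE under internal k-fold cross-validation, and the global minimizer is
#' returned. Deterministic given `seed` (fold assignment).
#'
#' @param XCal,yCal calibration data.
#' @param maxVars largest subset size considered (default 20;
#'   `<= min(channels, rows - 1)`).
#' @param seed fold-assignment seed.
#' @param kFolds number of internal CV folds (default 5).
#' @param wavelengths optional wavelength axis (nm) recorded in the result.
#' @return A [FeatureSelectionResult] with `method = "SPA"`; the winning
#'   chain's per-size subsets and CV RMSEs are in `@chainBySize`.
#' @export
spaSelect <- function(XCal, yCal, maxVars = 20L, seed = 1L, kFolds = 5L,
                      wavelengths = numeric()) {
  X <- assertMatrix(XCal)
  y <- as.numeric(yCal)
  n <- nrow(X); p <- ncol(X)
  maxVars <- as.integer(maxVars)
  if (maxVars > min(p, n - 1L))
    stop("maxVars must be <= min(channels, calibration rows - 1)")
  folds <- foldAssignments(n, kFolds, seed)
  # subset size is also capped so every CV training fold stays overdetermined
  sizeCap <- min(maxVars, n - max(table(folds)) - 1L)

  chains <- lapply(seq_len(p), function(start) spaChain(X, start, maxVars))

  best <- list(start = NA_integer_, size = NA_integer_, rmse = Inf)
  scores <- vector("list", p)
  for (start in seq_len(p)) {
    chain <- chains[[start]]
    sizes <- seq_len(min(length(chain), sizeCap))
    r <- vapply(sizes, function(s)
      sqrt(mlrCvSse(X, y, chain[seq_len(s)], folds) / n), numeric(1))
    scores[[start]] <- r
    k <- which.min(r)
    if (r[k] < best$rmse)
      best <- list(start = start, size = k, rmse = r[k])
  }

  chain <- chains[[best$start]]
  chainBySize <- lapply(seq_along(scores[[best$start]]), function(s)
    list(indices = chain[seq_len(s)], cvRmse = scores[[best$start]][s]))
  new("FeatureSelectionResult", method = "SPA",
      selectedIndices = as.integer(chain[seq_len(best$size)]),
      wavelengthAxis = as.numeric(wavelengths),
      stability = numeric(), hMax = numeric(),
      chainBySize = chainBySize)
}

# One SPA projection chain from a given starting column: repeatedly add the
# column with the largest norm after projection onto the orthogonal
# complement of the selected span (incremental Gram-Schmidt deflation).
spaChain <- function(X, start, maxVars) {
  Xp <- X
  sel <- integer(maxVars)
  sel[1] <- start
  len <- 1L
  while (len < maxVars) {
    s <- Xp[, sel[len]]
    ss <- sum(s^2)
    if (ss < 1e-24) break
    Xp <- Xp - tcrossprod(s / ss, as.vector(crossprod(Xp, s)))
    norms <- colSums(Xp^2)
    norms[sel[seq_len(len)]] <- -1
    nxt <- which.max(norms)                 # ties -> lowest channel index
    if (norms[nxt] < 1e-20) break           # remaining columns collinear
    len <- len + 1L
    sel[len] <- nxt
  }
  sel[seq_len(len)]
}

# Reference chain construction recomputing every projection from scratch via
# QR; used as an independent check of the incremental update.
spaChainBruteForce <- function(X, start, maxVars) {
  p <- ncol(X)
  sel <- start
  while (length(sel) < maxVars) {
    Q <- qr.Q(qr(X[, sel, drop = FALSE]))
    resid <- X - Q %*% crossprod(Q, X)
    norms <- colSums(resid^2)
    norms[sel] <- -1
    nxt <- which.max(norms)
    if (norms[nxt] < 1e-20) break
    sel <- c(sel, nxt)
  }
  sel
}

#' Uninformative variable elimination (UVE) wavelength selection
#'
#' Appends one artificial uniform-noise column per real channel (scaled by
#' `noiseScale`, small enough not to perturb the PLS model), runs
#' leave-one-out PLSR on the augmented matrix, and computes each variable's
#' stability s_j = mean(b_j) / SD(b_j) over the per-fold coefficient
#' vectors. The threshold h_max is the largest |s_j| over the noise columns;
#' real channels with |s_j| > h_max (strict) are kept, so no noise column
#' can ever be selected.
#'
#' @param XCal,yCal calibration data.
#' @param nLv number of PLS latent variables used inside UVE (typically
#'   chosen beforehand by [selectNComponents()] on the real channels).
#' @param noiseScale amplitude of the artificial noise columns
#'   (default 1e-10).
#' @param seed RNG seed for the noise draw.
#' @param wavelengths optional wavelength axis (nm) recorded in the result.
#' @return A [FeatureSelectionResult] with `method = "UVE"`, the stability
#'   profile over the 2p augmented variables and `hMax`.
#' @export
uveSelect <- function(XCal, yCal, nLv, noiseScale = 1e-10, seed = 1L,
                      wavelengths = numeric()) {
  X <- assertMatrix(XCal)
  y <- as.numeric(yCal)
  n <- nrow(X); p <- ncol(X)
  if (p < 1L) stop("need at least one channel")
  nLv <- as.integer(nLv)
  if (nLv >= n - 1L) stop("nLv must be < calibration rows - 1")
  noise <- withSeed(seed,
                    matrix(stats::runif(n * p), n, p)) * noiseScale
  A <- cbind(X, noise)
  B <- matrix(0, n, 2L * p)
  for (i in seq_len(n)) {
    m <- plsrFit(A[-i, , drop = FALSE], y[-i], nLv)
    B[i, ] <- m@coefficients
  }
  mu <- colMeans(B)
  sdv <- apply(B, 2L, stats::sd)
  stab <- mu / sdv
  degen <- sdv == 0
  # zero spread across folds: infinitely stable (signed), or dead variable
  stab[degen] <- sign(mu[degen]) * Inf
  stab[degen & mu == 0] <- 0
  hmax <- max(abs(stab[(p + 1L):(2L * p)]))
  keep <- which(abs(stab[seq_len(p)]) > hmax)
  new("FeatureSelectionResult", method = "UVE",
      selectedIndices = as.integer(keep),
      wavelengthAxis = as.numeric(wavelengths),
      stability = stab, hMax = hmax, chainBySize = list())
}
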