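#' Savitzky-Golay smoothing of spectra
#'
#' Moving least-squares polynomial convolution applied row-wise (per
#' spectrum). Interior points use the standard convolution weights; boundary
#' points are obtained from the polynomial fitted to the first/last window,
#' so the output keeps the input length and channel indexing. Polynomials of
#' degree `<= polyorder` are fixed points.
#'
#' @param X matrix, measurements x channels.
#' @param window odd window length (default 5 points).
#' @param polyorder polynomial order (default 2, `< window`).
#' @return Matrix of the same shape.
#' @export
sgSmooth <- function(X, window = 5L, polyorder = 2L) {
  X <- assertMatrix(X)
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  if (window %% 2L == 0L || window < 3L)
    stop("window must be odd and >= 3")
  if (polyorder >= window) stop("polyorder must be < window")
  if (window > ncol(X)) stop("window must be <= the number of channels")
  out <- t(apply(X, 1L, signal::sgolayfilt, p = polyorder, n = window))
  dimnames(out) <- dimnames(X)
  out
}

#' Fit a multiplicative scatter correction model
#'
#' The MSC reference is the mean of the calibration spectra only; fitting on
#' calibration rows and applying to held-out rows avoids train/test leakage.
#'
#' @param XCal calibration matrix, measurements x channels (>= 2 rows).
#' @return An [MSCModel].
#' @export
mscFit <- function(XCal) {
  XCal <- assertMatrix(XCal)
  if (nrow(XCal) < 2) stop("MSC needs at least 2 calibration spectra")
  m <- colMeans(XCal)
  if (stats::sd(m) == 0)
    stop("degenerate reference: mean calibration spectrum is constant")
  new("MSCModel", referenceMean = m)
}

#' Apply multiplicative scatter correction
#'
#' Each row is regressed (OLS) on the reference mean spectrum giving
#' intercept b0 and slope b; the corrected row is (row - b0) / b.
#'
#' @param model an [MSCModel] from [mscFit()].
#' @param X matrix to correct (same channel count as the model).
#' @return Corrected matrix of the same shape.
#' @export
mscApply <- function(model, X) {
  stopifnot(is(model, "MSCModel"))
  X <- assertMatrix(X)
  ref <- model@referenceMean
  if (ncol(X) != length(ref))
    stop("channel count does not match the MSC model")
  refC <- ref - mean(ref)
  ss <- sum(refC^2)
  b <- as.vector(X %*% refC) / ss          # per-row OLS slope on the reference
  b0 <- rowMeans(X) - b * mean(ref)
  if (any(abs(b) < 1e-12)) {
    bad <- which(abs(b) < 1e-12)[1]
    stop("degenerate sample: spectrum ", bad,
         " has near-zero slope against the reference")
  }
  out <- (X - b0) / b
  dimnames(out) <- dimnames(X)
  out
}

#' Standard normal variate transform
#'
#' Each spectrum is centered by its own mean and scaled by its own sample
#' standard deviation (n-1 denominator), making the result invariant to
#' per-spectrum affine distortions a + b*x (b > 0).
#'
#' @param X matrix, measurements x channels (>= 2 channels).
#' @return Transformed matrix.
#' @export
snv <- function(X) {
  X <- assertMatrix(X)
  mu <- rowMeans(X)
  s <- apply(X, 1L, stats::sd)
  if (any(s == 0))
    stop("zero-variance spectrum in row ", which(s == 0)[1])
  out <- (X - mu) / s
  dimnames(out) <- dimnames(X)
  out
}

#' First derivative of spectra with respect to wavelength
#'
#' Central differences at interior channels scaled by the actual wavelength
#' spacing, one-sided differences at the two ends; removes
#' wavelength-independent baseline offsets.
#'
#' @param X matrix, measurements x channels (>= 3 channels).
#' @param wavelengths strictly increasing channel wavelengths, nm.
#' @return Matrix of the same shape, units of absorbance per nm.
#' @export
firstDerivative <- function(X, wavelengths) {
  X <- assertMatrix(X)
  p <- ncol(X)
  if (p < 3) stop("first derivative needs at least 3 channels")
  if (length(wavelengths) != p || any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing and match the channels")
  out <- X
  out[, 1] <- (X[, 2] - X[, 1]) / (wavelengths[2] - wavelengths[1])
  out[, p] <- (X[, p] - X[, p - 1]) / (wavelengths[p] - wavelengths[p - 1])
  j <- 2:(p - 1)
  out[, j] <- (X[, j + 1, drop = FALSE] - X[, j - 1, drop = FALSE]) /
    rep(wavelengths[j + 1] - wavelengths[j - 1], each = nrow(X))
  out
}

#' Apply one of the eight preprocessing variants
#'
#' Variants: `"X"` (pass-through), `"SG"`, `"MSC"`, `"SNV"`, `"1D"`,
#' `"1D+SG"`, `"1D+MSC"`, `"1D+SNV"`. Combined variants apply the first
#' derivative FIRST, then the named second step. Stateful steps (MSC) are
#' fitted on the (transformed) calibration rows only and applied unchanged
#' to the prediction rows.
#'
#' @param spec a [PreprocessSpec] or one of the variant names.
#' @param XCal,XPred calibration and prediction matrices with matching
#'   channel counts (`XPred` may be `NULL`).
#' @param wavelengths channel wavelengths, needed for derivative variants.
#' @return List with elements `calibration` and `prediction` (the latter
#'   `NULL` if `XPred` was).
#' @examples
#' wl <- seq(940, 1660, length.out = 16)
#' X <- matrix(rnorm(64), 4, 16)
#' out <- applyPreprocessing("1D+SNV", X[1:3, ], X[4, , drop = FALSE], wl)
#' rowMeans(out$calibration)
#' @export
applyPreprocessing <- function(spec, XCal, XPred = NULL, wavelengths = NULL) {
  if (is.character(spec)) spec <- preprocessSpec(spec)
  stopifnot(is(spec, "PreprocessSpec"))
  validObject(spec)
  XCal <- assertMatrix(XCal)
  if (!is.null(XPred)) {
    XPred <- assertMatrix(XPred)
    if (ncol(XPred) != ncol(XCal))
      stop("calibration and prediction channel counts differ")
  }
  name <- spec@name
  steps <- strsplit(name, "+", fixed = TRUE)[[1]]
  if (identical(steps, "X")) steps <- character()
  for (step in steps) {
    if (step == "1D") {
      if (is.null(wavelengths))
        stop("derivative preprocessing needs the wavelength axis")
      XCal <- firstDerivative(XCal, wavelengths)
      if (!is.null(XPred)) XPred <- firstDerivative(XPred, wavelengths)
    } else if (step == "SG") {
      XCal <- sgSmooth(XCal, spec@sgWindow, spec@sgPolyorder)
      if (!is.null(XPred)) XPred <- sgSmooth(XPred, spec@sgWindow,
                                             spec@sgPolyorder)
    } else if (step == "MSC") {
      m <- mscFit(XCal)
      XCal <- mscApply(m, XCal)
      if (!is.null(XPred)) XPred <- mscApply(m, XPred)
    } else if (step == "SNV") {
      XCal <- snv(XCal)
      if (!is.null(XPred)) XPred <- snv(XPred)
    } else stop("unknown preprocessing step '", step, "'")
  }
  list(calibration = XCal, prediction = XPred)
}
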