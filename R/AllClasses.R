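#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata
NULL

# ---------------------------------------------------------------------------
# SpectraSet
# ---------------------------------------------------------------------------

#' SpectraSet: a set of NIR spectra with a shared wavelength axis
#'
#' `SpectraSet` extends [SummarizedExperiment::SummarizedExperiment]. The
#' single assay `"intensity"` holds wavelength channels as rows and
#' measurements as columns; `rowData()$wavelength` carries the axis in nm and
#' `colData()` carries `sample_id` (repeated across replicate measurements)
#' and the unique `measurement_id`. Most workflow functions consume the
#' transposed view returned by [intensityMatrix()] (measurements x channels).
#'
#' @slot .Data see `SummarizedExperiment`.
#' @export
setClass("SpectraSet", contains = "SummarizedExperiment")

#' Construct a SpectraSet
#'
#' @param intensities numeric matrix, measurements x channels; no missing
#'   values.
#' @param wavelengths numeric vector of channel wavelengths in nm, strictly
#'   increasing, length `ncol(intensities)`.
#' @param sampleIds character vector, one per measurement; repeated ids mark
#'   replicate measurements of the same physical sample.
#' @param measurementIds character vector of unique measurement identifiers;
#'   defaults to `sampleIds` suffixed with a replicate counter.
#' @return A [SpectraSet].
#' @examples
#' s <- SpectraSet(matrix(1:6, 2, 3), c(940, 1300, 1660),
#'                 sampleIds = c("a", "b"))
#' wavelengths(s)
#' @export
SpectraSet <- function(intensities, wavelengths, sampleIds,
                       measurementIds = NULL) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (is.null(measurementIds)) {
    measurementIds <- stats::ave(sampleIds, sampleIds,
                                 FUN = function(z) paste0(z, "_r", seq_along(z)))
  }
  se <- SummarizedExperiment(
    assays = list(intensity = t(intensities)),
    rowData = DataFrame(wavelength = as.numeric(wavelengths)),
    colData = DataFrame(sample_id = as.character(sampleIds),
                        measurement_id = as.character(measurementIds),
                        row.names = as.character(measurementIds)))
  rownames(se) <- format(as.numeric(wavelengths), trim = TRUE)
  new("SpectraSet", se)
}

setValidity("SpectraSet", function(object) {
  msg <- character()
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  wl <- rowData(object)$wavelength
  if (is.null(wl))
    msg <- c(msg, "rowData must contain a 'wavelength' column")
  else {
    if (anyNA(wl) || any(diff(wl) <= 0))
      msg <- c(msg, "wavelengths must be strictly increasing and non-missing")
  }
  cd <- colData(object)
  if (!all(c("sample_id", "measurement_id") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'sample_id' and 'measurement_id'")
  else if (anyDuplicated(cd$measurement_id))
    msg <- c(msg, "measurement ids must be unique")
  if (length(msg) == 0 && anyNA(assay(object, "intensity")))
    msg <- c(msg, "intensity matrix must not contain missing values")
  if (length(msg)) msg else TRUE
})

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "SpectraSet", function(x) rowData(x)$wavelength)

#' @rdname intensityMatrix
#' @export
setMethod("intensityMatrix", "SpectraSet", function(x) {
  m <- t(assay(x, "intensity"))
  dimnames(m) <- list(colData(x)$measurement_id,
                      format(wavelengths(x), trim = TRUE))
  m
})

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "SpectraSet", function(x) colData(x)$sample_id)

#' @rdname measurementIds
#' @export
setMethod("measurementIds", "SpectraSet", function(x) colData(x)$measurement_id)

setMethod("show", "SpectraSet", function(object) {
  wl <- wavelengths(object)
  cat("SpectraSet:", ncol(object), "measurements from",
      length(unique(sampleIds(object))), "samples\n")
  cat(sprintf("  %d channels, %.1f-%.1f nm\n", length(wl), min(wl), max(wl)))
})

# ---------------------------------------------------------------------------
# SyntheticConfig
# ---------------------------------------------------------------------------

#' Configuration of the synthetic spectra generator
#'
#' Defines the sample statistics, band chemistry and measurement degradations
#' emulated by [generateSpectra()]. Defaults reproduce the study conditions
#' the package's acceptance checks assume: 92 samples x 3 replicate
#' measurements on a 128-channel grid over 940-1660 nm, protein content
#' truncated-normal with mean 9.79%, SD 0.7%, range 8.43-11.25%, and
#' protein-linked absorption bands at 994, 1212 and 1466 nm. See
#' [syntheticConfig()].
#'
#' @slot nSamples,nReplicates,nChannels integer counts.
#' @slot wlMin,wlMax wavelength range, nm.
#' @slot proteinMean,proteinSd,proteinMin,proteinMax protein content, % mass.
#' @slot proteinBandCenters,proteinBandWidths numeric, nm (Gaussian SD).
#' @slot proteinBandStrengths numeric, absorbance units per % protein.
#' @slot interferentBandCenters,interferentBandWidths numeric, nm.
#' @slot interferentBandStrengths numeric, absorbance units per % constituent.
#' @slot interferentMean,interferentSd interferent constituent content, %.
#' @slot scatterSlopeSd SD of per-measurement multiplicative scatter (around 1).
#' @slot scatterOffsetSd SD of per-measurement additive offset, absorbance.
#' @slot driftAmplitude SD of per-measurement linear baseline drift slope,
#'   absorbance per normalized wavelength.
#' @slot noiseSd per-channel Gaussian noise SD, absorbance.
#' @slot seed integer RNG seed.
#' @export
setClass("SyntheticConfig",
  representation(
    nSamples = "integer", nReplicates = "integer", nChannels = "integer",
    wlMin = "numeric", wlMax = "numeric",
    proteinMean = "numeric", proteinSd = "numeric",
    proteinMin = "numeric", proteinMax = "numeric",
    proteinBandCenters = "numeric", proteinBandWidths = "numeric",
    proteinBandStrengths = "numeric",
    interferentBandCenters = "numeric", interferentBandWidths = "numeric",
    interferentBandStrengths = "numeric",
    interferentMean = "numeric", interferentSd = "numeric",
    scatterSlopeSd = "numeric", scatterOffsetSd = "numeric",
    driftAmplitude = "numeric", noiseSd = "numeric",
    seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (object@wlMin >= object@wlMax) msg <- c(msg, "wlMin must be < wlMax")
  if (object@nChannels < 2L) msg <- c(msg, "nChannels must be >= 2")
  if (object@nSamples < 1L || object@nReplicates < 1L)
    msg <- c(msg, "nSamples and nReplicates must be >= 1")
  if (!(object@proteinMin <= object@proteinMean &&
        object@proteinMean <= object@proteinMax))
    msg <- c(msg, "need proteinMin <= proteinMean <= proteinMax")
  sds <- c(object@proteinSd, object@scatterSlopeSd, object@scatterOffsetSd,
           object@driftAmplitude, object@noiseSd, object@interferentSd)
  if (any(sds < 0)) msg <- c(msg, "all SDs must be >= 0")
  ctr <- c(object@proteinBandCenters, object@interferentBandCenters)
  if (any(ctr < object@wlMin | ctr > object@wlMax))
    msg <- c(msg, "band centers must lie within [wlMin, wlMax]")
  if (length(object@proteinBandWidths) != length(object@proteinBandCenters) ||
      length(object@proteinBandStrengths) != length(object@proteinBandCenters))
    msg <- c(msg, "protein band centers/widths/strengths lengths differ")
  if (length(object@interferentBandWidths) != length(object@interferentBandCenters) ||
      length(object@interferentBandStrengths) != length(object@interferentBandCenters))
    msg <- c(msg, "interferent band centers/widths/strengths lengths differ")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf("SyntheticConfig: %d samples x %d replicates, %d channels (%g-%g nm)\n",
              object@nSamples, object@nReplicates, object@nChannels,
              object@wlMin, object@wlMax))
  cat(sprintf("  protein ~ truncN(%.2f, %.2f) on [%.2f, %.2f] %%\n",
              object@proteinMean, object@proteinSd,
              object@proteinMin, object@proteinMax))
  cat(sprintf("  protein bands at %s nm; %d interferent bands\n",
              paste(object@proteinBandCenters, collapse = ", "),
              length(object@interferentBandCenters)))
  cat(sprintf("  scatter slope/offset SD %g/%g, drift %g, noise %g, seed %d\n",
              object@scatterSlopeSd, object@scatterOffsetSd,
              object@driftAmplitude, object@noiseSd, object@seed))
})

# ---------------------------------------------------------------------------
# PreprocessSpec / MSCModel
# ---------------------------------------------------------------------------

#' Preprocessing variant specification
#'
#' One of the eight variants: `"X"` (raw), `"SG"`, `"MSC"`, `"SNV"`, `"1D"`,
#' `"1D+SG"`, `"1D+MSC"`, `"1D+SNV"`. Combined variants apply the first
#' derivative first. See [applyPreprocessing()].
#'
#' @slot name variant name.
#' @slot sgWindow odd Savitzky-Golay window length (default 5).
#' @slot sgPolyorder Savitzky-Golay polynomial order (default 2).
#' @export
setClass("PreprocessSpec",
  representation(name = "character", sgWindow = "integer",
                 sgPolyorder = "integer"))

#' @rdname PreprocessSpec-class
#' @param name,sgWindow,sgPolyorder see slots.
#' @export
preprocessSpec <- function(name, sgWindow = 5L, sgPolyorder = 2L) {
  new("PreprocessSpec", name = as.character(name),
      sgWindow = as.integer(sgWindow), sgPolyorder = as.integer(sgPolyorder))
}

preprocessingNames <- function()
  c("X", "SG", "MSC", "SNV", "1D", "1D+SG", "1D+MSC", "1D+SNV")

setValidity("PreprocessSpec", function(object) {
  msg <- character()
  if (!object@name %in% preprocessingNames())
    msg <- c(msg, paste0("unknown preprocessing '", object@name, "'"))
  if (object@sgWindow < 3L || object@sgWindow %% 2L == 0L)
    msg <- c(msg, "sgWindow must be odd and >= 3")
  if (object@sgPolyorder >= object@sgWindow)
    msg <- c(msg, "sgPolyorder must be < sgWindow")
  if (length(msg)) msg else TRUE
})

#' Multiplicative scatter correction model
#'
#' Holds the calibration-set mean spectrum against which each spectrum is
#' regressed; the correction is (x - b0) / b with per-spectrum OLS intercept
#' b0 and slope b. Fit with [mscFit()], apply with [mscApply()].
#'
#' @slot referenceMean mean calibration spectrum.
#' @export
setClass("MSCModel", representation(referenceMean = "numeric"))

setValidity("MSCModel", function(object) {
  if (length(object@referenceMean) < 2 ||
      stats::sd(object@referenceMean) == 0)
    "referenceMean must be a non-constant spectrum" else TRUE
})

# ---------------------------------------------------------------------------
# Regression models
# ---------------------------------------------------------------------------

#' NIPALS partial least squares regression model
#'
#' @slot nComponents number of latent variables retained.
#' @slot weights,loadings p x A weight (W) and X-loading (P) matrices.
#' @slot yLoadings per-component y loadings q.
#' @slot scores n x A orthogonal score matrix T.
#' @slot xMean,yMean centering statistics from the training data.
#' @slot coefficients regression coefficients for `nComponents` components,
#'   on centered X / centered y scale.
#' @export
setClass("PLSRModel",
  representation(nComponents = "integer", weights = "matrix",
                 loadings = "matrix", yLoadings = "numeric",
                 scores = "matrix", xMean = "numeric", yMean = "numeric",
                 coefficients = "numeric"))

setValidity("PLSRModel", function(object) {
  msg <- character()
  a <- object@nComponents
  if (a < 1L) msg <- c(msg, "nComponents must be >= 1")
  if (ncol(object@weights) != a || ncol(object@scores) != a)
    msg <- c(msg, "weights/scores must have nComponents columns")
  if (a > 1L) {
    tt <- crossprod(object@scores)
    off <- max(abs(tt[upper.tri(tt)])) / max(diag(tt))
    if (off > 1e-8)
      msg <- c(msg, "component scores must be mutually orthogonal")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "PLSRModel", function(object) {
  cat(sprintf("PLSRModel (NIPALS): %d latent variables, %d channels\n",
              object@nComponents, length(object@xMean)))
})

#' Epsilon-support-vector regression model
#'
#' Thin wrapper around the fitted libsvm object (via e1071) recording the
#' kernel and tuning parameters. `gamma` maps to the RBF width via
#' g = 1 / (2 sigma^2); it is `NA` for the linear kernel.
#'
#' @slot kernel `"linear"` or `"rbf"`.
#' @slot cost penalty parameter c (> 0).
#' @slot gamma RBF kernel parameter g (> 0 for rbf, `NA` for linear).
#' @slot epsilon insensitive-tube half-width, in y units.
#' @slot fit the underlying `e1071::svm` fit.
#' @export
setClass("SVRModel",
  representation(kernel = "character", cost = "numeric", gamma = "numeric",
                 epsilon = "numeric", fit = "ANY"))

setValidity("SVRModel", function(object) {
  msg <- character()
  if (!object@kernel %in% c("linear", "rbf"))
    msg <- c(msg, "kernel must be 'linear' or 'rbf'")
  if (object@cost <= 0) msg <- c(msg, "cost must be > 0")
  if (object@kernel == "rbf" && !(is.finite(object@gamma) && object@gamma > 0))
    msg <- c(msg, "gamma must be > 0 for the rbf kernel")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SVRModel", function(object) {
  cat(sprintf("SVRModel: %s kernel, c = %g%s, epsilon = %g\n",
              object@kernel, object@cost,
              if (object@kernel == "rbf") sprintf(", g = %g", object@gamma) else "",
              object@epsilon))
})

#' Extreme learning machine regression model
#'
#' Single-hidden-layer feedforward network with random fixed input weights
#' and analytically solved output weights (Moore-Penrose pseudoinverse of the
#' hidden-layer activations). Inputs are min-max scaled to [-1, 1] with
#' bounds stored from the training data.
#'
#' @slot nNeurons hidden-layer size.
#' @slot inputWeights p x L input weight matrix (uniform(-1, 1)).
#' @slot biases length-L hidden biases (uniform(-1, 1)).
#' @slot outputWeights length-L least-squares output weights.
#' @slot xMin,xMax training-data per-channel scaling bounds.
#' @slot seed RNG seed used for the random layer.
#' @export
setClass("ELMModel",
  representation(nNeurons = "integer", inputWeights = "matrix",
                 biases = "numeric", outputWeights = "numeric",
                 xMin = "numeric", xMax = "numeric", seed = "integer"))

setValidity("ELMModel", function(object) {
  if (object@nNeurons < 1L) "nNeurons must be >= 1" else TRUE
})

setMethod("show", "ELMModel", function(object) {
  cat(sprintf("ELMModel: %d hidden neurons, sigmoid activation, seed %d\n",
              object@nNeurons, object@seed))
})

# ---------------------------------------------------------------------------
# FeatureSelectionResult
# ---------------------------------------------------------------------------

#' Result of SPA or UVE wavelength selection
#'
#' @slot method `"SPA"` or `"UVE"`.
#' @slot selectedIndices channel indices in selection order (SPA) or
#'   ascending (UVE); unique, within the real channels.
#' @slot wavelengthAxis full wavelength axis in nm (may be empty if the
#'   selection was run on a bare matrix).
#' @slot stability UVE only: stability over real then noise variables
#'   (length 2p); empty for SPA.
#' @slot hMax UVE only: max |stability| over the noise variables.
#' @slot chainBySize SPA only: for the winning start, per subset size a list
#'   with elements `indices` and `cvRmse`.
#' @export
setClass("FeatureSelectionResult",
  representation(method = "character", selectedIndices = "integer",
                 wavelengthAxis = "numeric", stability = "numeric",
                 hMax = "numeric", chainBySize = "list"))

setValidity("FeatureSelectionResult", function(object) {
  msg <- character()
  if (!object@method %in% c("SPA", "UVE"))
    msg <- c(msg, "method must be 'SPA' or 'UVE'")
  idx <- object@selectedIndices
  if (anyDuplicated(idx)) msg <- c(msg, "selected indices must be unique")
  if (length(idx) && min(idx) < 1L)
    msg <- c(msg, "selected indices must be >= 1")
  if (object@method == "UVE" && length(object@stability)) {
    p <- length(object@stability) %/% 2L
    if (length(idx) && max(idx) > p)
      msg <- c(msg, "UVE selection must stay within the real channels")
    else if (length(object@hMax) == 1 && length(idx) &&
             any(abs(object@stability[idx]) <= object@hMax))
      msg <- c(msg, "every selected channel must satisfy |stability| > hMax")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname selectedIndices
#' @export
setMethod("selectedIndices", "FeatureSelectionResult",
          function(x) x@selectedIndices)

#' @rdname selectedWavelengths
#' @export
setMethod("selectedWavelengths", "FeatureSelectionResult", function(x) {
  if (!length(x@wavelengthAxis)) stop("no wavelength axis recorded")
  x@wavelengthAxis[x@selectedIndices]
})

#' @rdname stabilityProfile
#' @export
setMethod("stabilityProfile", "FeatureSelectionResult", function(x) x@stability)

#' @rdname hMax
#' @export
setMethod("hMax", "FeatureSelectionResult", function(x) x@hMax)

setMethod("show", "FeatureSelectionResult", function(object) {
  cat(sprintf("FeatureSelectionResult (%s): %d channels selected\n",
              object@method, length(object@selectedIndices)))
  if (object@method == "UVE" && length(object@hMax))
    cat(sprintf("  h_max = %.3f over %d noise variables\n", object@hMax,
                length(object@stability) %/% 2L))
})

# ---------------------------------------------------------------------------
# Partition / EvaluationReport
# ---------------------------------------------------------------------------

#' Disjoint calibration/prediction partition of a sample set
#'
#' Produced by [concentrationGradientSplit()]; the prediction-set reference
#' range is contained in the calibration-set range by construction.
#'
#' @slot calibration,prediction integer sample indices.
#' @export
setClass("Partition",
  representation(calibration = "integer", prediction = "integer"))

setValidity("Partition", function(object) {
  msg <- character()
  if (length(intersect(object@calibration, object@prediction)))
    msg <- c(msg, "calibration and prediction sets must be disjoint")
  n <- length(object@calibration) + length(object@prediction)
  if (!setequal(c(object@calibration, object@prediction), seq_len(n)))
    msg <- c(msg, "partition must cover all samples exactly once")
  if (length(msg)) msg else TRUE
})

#' @rdname calibrationIndices
#' @export
setMethod("calibrationIndices", "Partition", function(x) x@calibration)

#' @rdname predictionIndices
#' @export
setMethod("predictionIndices", "Partition", function(x) x@prediction)

setMethod("show", "Partition", function(object) {
  cat(sprintf("Partition: %d calibration / %d prediction samples\n",
              length(object@calibration), length(object@prediction)))
})

#' Evaluation report for one preprocessing x selection x model run
#'
#' Metrics follow the workflow's printed conventions: `rC`/`rP` are
#' 1 - SSres/SStot, `rmseC`/`rmseP` use an N-1 denominator, and
#' `rpd = sdPrediction / rmseP` where `sdPrediction` is the sample SD of the
#' prediction-set reference values.
#'
#' @slot rC,rmseC,rP,rmseP,rpd,sdPrediction numeric metrics.
#' @slot nCal,nPred sample counts.
#' @slot info free-form metadata (preprocessing, model, hyperparameters,
#'   seed, number of bands, ...).
#' @export
setClass("EvaluationReport",
  representation(rC = "numeric", rmseC = "numeric", rP = "numeric",
                 rmseP = "numeric", rpd = "numeric",
                 sdPrediction = "numeric", nCal = "integer",
                 nPred = "integer", info = "list"))

setValidity("EvaluationReport", function(object) {
  msg <- character()
  if (any(c(object@rmseC, object@rmseP) < 0))
    msg <- c(msg, "RMSE must be >= 0")
  if (is.finite(object@rpd) &&
      abs(object@rpd * object@rmseP - object@sdPrediction) > 1e-12 *
        max(1, object@sdPrediction))
    msg <- c(msg, "rpd must equal sdPrediction / rmseP exactly")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EvaluationReport", function(object) {
  lbl <- paste(unlist(object@info[c("preprocessing", "selection", "model")]),
               collapse = " / ")
  if (nzchar(lbl)) cat("Run:", lbl, "\n")
  cat(sprintf("  n_cal = %d, n_pred = %d\n", object@nCal, object@nPred))
  cat(sprintf("  R_c = %.2f, RMSE_c = %.2f, R_p = %.2f, RMSE_p = %.2f, RPD = %.2f\n",
              object@rC, object@rmseC, object@rP, object@rmseP, object@rpd))
  cat("  interpretation:", rpdBand(object@rpd), "\n")
})
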