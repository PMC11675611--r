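#' @import methods
#' @importFrom stats predict
NULL

#' Wavelength axis of a spectral object
#'
#' @param x an object with a wavelength axis (e.g. a [SpectraSet]).
#' @return Numeric vector of wavelengths in nm, strictly increasing.
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' Intensity matrix of a SpectraSet
#'
#' Returns the spectra in the orientation used throughout the calibration
#' workflow: one row per measurement, one column per wavelength channel.
#'
#' @param x a [SpectraSet].
#' @return Numeric matrix, measurements x channels.
#' @export
setGeneric("intensityMatrix", function(x) standardGeneric("intensityMatrix"))

#' Sample identifiers (one per measurement, repeated across replicates)
#' @param x a [SpectraSet].
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Unique measurement identifiers
#' @param x a [SpectraSet].
#' @export
setGeneric("measurementIds", function(x) standardGeneric("measurementIds"))

#' Average replicate measurements per sample
#'
#' Collapses a replicated [SpectraSet] to one spectrum per sample by
#' channel-wise arithmetic mean, keeping first-appearance sample order.
#' Idempotent on already-averaged sets.
#'
#' @param x a [SpectraSet].
#' @return A [SpectraSet] with one row per unique sample id.
#' @export
setGeneric("averageReplicates", function(x) standardGeneric("averageReplicates"))

#' Selected channel indices of a feature-selection result
#' @param x a [FeatureSelectionResult].
#' @export
setGeneric("selectedIndices", function(x) standardGeneric("selectedIndices"))

#' Selected wavelengths (nm) of a feature-selection result
#' @param x a [FeatureSelectionResult].
#' @export
setGeneric("selectedWavelengths", function(x) standardGeneric("selectedWavelengths"))

#' UVE stability profile over real + noise variables
#' @param x a [FeatureSelectionResult] from [uveSelect()].
#' @export
setGeneric("stabilityProfile", function(x) standardGeneric("stabilityProfile"))

#' UVE stability threshold h_max
#' @param x a [FeatureSelectionResult] from [uveSelect()].
#' @export
setGeneric("hMax", function(x) standardGeneric("hMax"))

#' Calibration-set indices of a Partition
#' @param x a [Partition].
#' @export
setGeneric("calibrationIndices", function(x) standardGeneric("calibrationIndices"))

#' Prediction-set indices of a Partition
#' @param x a [Partition].
#' @export
setGeneric("predictionIndices", function(x) standardGeneric("predictionIndices"))
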