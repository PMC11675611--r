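#' Read spectra from a wide CSV file
#'
#' Expected dialect: comma-separated, UTF-8, '.' decimal; first two columns
#' `sample_id` and `measurement_id`, remaining column headers the numeric
#' channel wavelengths in nm (strictly increasing), one row per measurement.
#'
#' @param path file path.
#' @return A [SpectraSet].
#' @seealso [writeSpectraCsv()]
#' @export
readSpectraCsv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3 || !identical(colnames(df)[1:2],
                                 c("sample_id", "measurement_id")))
    stop("spectra CSV must start with columns 'sample_id', 'measurement_id' ",
         "followed by numeric wavelength columns")
  wlNames <- colnames(df)[-(1:2)]
  wl <- suppressWarnings(as.numeric(wlNames))
  if (anyNA(wl))
    stop("non-numeric wavelength column header(s): ",
         paste(wlNames[is.na(wl)], collapse = ", "))
  bad <- which(diff(wl) <= 0)
  if (length(bad))
    stop("wavelength headers not strictly increasing at column '",
         wlNames[bad[1] + 1], "'")
  M <- as.matrix(df[, -(1:2), drop = FALSE])
  if (anyNA(M)) {
    loc <- which(is.na(M), arr.ind = TRUE)[1, ]
    stop(sprintf("missing intensity value at row %d, column '%s'",
                 loc["row"], wlNames[loc["col"]]))
  }
  SpectraSet(M, wl, sampleIds = as.character(df$sample_id),
             measurementIds = as.character(df$measurement_id))
}

#' Write spectra to a wide CSV file
#'
#' @param x a [SpectraSet].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSpectraCsv <- function(x, path) {
  stopifnot(is(x, "SpectraSet"))
  M <- intensityMatrix(x)
  df <- data.frame(sample_id = sampleIds(x),
                   measurement_id = measurementIds(x),
                   M, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("sample_id", "measurement_id",
                    format(wavelengths(x), trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a reference table of protein contents
#'
#' Columns `sample_id`, `protein_pct` (% mass, > 0), unique sample ids.
#'
#' @param path file path.
#' @return A data.frame with columns `sample_id`, `protein`.
#' @export
readReferenceCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "protein_pct") %in% colnames(df)))
    stop("reference CSV must have columns 'sample_id', 'protein_pct'")
  ref <- data.frame(sample_id = as.character(df$sample_id),
                    protein = as.numeric(df$protein_pct),
                    stringsAsFactors = FALSE)
  validateReference(ref)
  ref
}

#' Write a reference table of protein contents
#'
#' @param reference data.frame with columns `sample_id`, `protein`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeReferenceCsv <- function(reference, path) {
  validateReference(reference)
  utils::write.csv(data.frame(sample_id = reference$sample_id,
                              protein_pct = reference$protein),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validateReference <- function(reference) {
  if (!all(c("sample_id", "protein") %in% colnames(reference)))
    stop("reference table must have columns 'sample_id', 'protein'")
  if (anyDuplicated(reference$sample_id))
    stop("reference sample ids must be unique")
  if (anyNA(reference$protein) || any(reference$protein <= 0))
    stop("protein contents must be positive and non-missing")
  invisible(reference)
}

#' @rdname averageReplicates
#' @export
setMethod("averageReplicates", "SpectraSet", function(x) {
  ids <- sampleIds(x)
  uniq <- unique(ids)                      # first-appearance order
  grp <- factor(ids, levels = uniq)
  M <- intensityMatrix(x)
  avg <- rowsum(M, grp) / as.vector(table(grp))
  SpectraSet(avg, wavelengths(x), sampleIds = uniq, measurementIds = uniq)
})

#' Align a SpectraSet with a reference table
#'
#' Returns the X block (measurements x channels) and the y vector of protein
#' contents row-aligned with it, preserving the spectra's measurement order.
#'
#' @param spectra a [SpectraSet] (typically after [averageReplicates()]).
#' @param reference data.frame with columns `sample_id`, `protein`; must
#'   cover every sample id present in `spectra`.
#' @return A list with elements `X` (matrix), `y` (numeric) and
#'   `wavelengths`.
#' @export
joinReference <- function(spectra, reference) {
  stopifnot(is(spectra, "SpectraSet"))
  validateReference(reference)
  ids <- sampleIds(spectra)
  pos <- match(ids, reference$sample_id)
  if (anyNA(pos))
    stop("sample id(s) missing from reference table: ",
         paste(unique(ids[is.na(pos)]), collapse = ", "))
  list(X = intensityMatrix(spectra), y = reference$protein[pos],
       wavelengths = wavelengths(spectra))
}
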