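#' Build a synthetic spectra generator configuration
#'
#' The generator emulates diffuse-reflectance NIR measurements of ground
#' grain: a Beer-Lambert-style sum of Gaussian absorption bands (three
#' protein-linked bands plus independent interferent bands), degraded per
#' measurement by multiplicative/additive scatter, linear baseline drift and
#' channel noise. These are exactly the degradation families that MSC, SNV
#' and derivative preprocessing are designed to remove, so parameter-recovery
#' tests on this generator are informative about the workflow.
#'
#' @param nSamples,nReplicates,nChannels counts (defaults 92, 3, 128).
#' @param wlMin,wlMax wavelength range in nm (defaults 940, 1660).
#' @param proteinMean,proteinSd,proteinMin,proteinMax protein content
#'   distribution in % mass (defaults 9.79, 0.7, 8.43, 11.25; truncated
#'   normal).
#' @param proteinBandCenters,proteinBandWidths,proteinBandStrengths
#'   protein-linked Gaussian bands: centers (nm; defaults 994, 1212,
#'   1466), widths (Gaussian SD, nm) and strengths (absorbance per
#'   % protein).
#' @param interferentBandCenters,interferentBandWidths,interferentBandStrengths
#'   bands of matrix constituents whose concentrations are independent of
#'   protein; they overlap the protein bands the way starch/water bands do in
#'   real grain, so variable selection has something to reject and model
#'   accuracy is bounded away from perfection.
#' @param interferentMean,interferentSd per-sample interferent constituent
#'   content, % (normal).
#' @param scatterSlopeSd,scatterOffsetSd per-measurement multiplicative
#'   (around 1) and additive scatter SDs.
#' @param driftAmplitude SD of the per-measurement linear baseline slope,
#'   absorbance per normalized wavelength.
#' @param noiseSd per-channel Gaussian noise SD, absorbance.
#' @param seed integer RNG seed.
#' @return A validated [SyntheticConfig].
#' @examples
#' cfg <- syntheticConfig(seed = 1)
#' cfg
#' @export
syntheticConfig <- function(nSamples = 92L, nReplicates = 3L,
                            nChannels = 128L, wlMin = 940, wlMax = 1660,
                            proteinMean = 9.79, proteinSd = 0.7,
                            proteinMin = 8.43, proteinMax = 11.25,
                            proteinBandCenters = c(994, 1212, 1466),
                            proteinBandWidths = c(28, 32, 36),
                            proteinBandStrengths = c(0.020, 0.026, 0.022),
                            interferentBandCenters = c(1000, 1200, 1460, 1590),
                            interferentBandWidths = c(150, 180, 120, 80),
                            interferentBandStrengths = c(0.013, 0.015, 0.017, 0.010),
                            interferentMean = 75, interferentSd = 2.5,
                            scatterSlopeSd = 0.10, scatterOffsetSd = 0.02,
                            driftAmplitude = 0.05, noiseSd = 0.002,
                            seed = 1L) {
  new("SyntheticConfig",
      nSamples = as.integer(nSamples), nReplicates = as.integer(nReplicates),
      nChannels = as.integer(nChannels), wlMin = wlMin, wlMax = wlMax,
      proteinMean = proteinMean, proteinSd = proteinSd,
      proteinMin = proteinMin, proteinMax = proteinMax,
      proteinBandCenters = proteinBandCenters,
      proteinBandWidths = proteinBandWidths,
      proteinBandStrengths = proteinBandStrengths,
      interferentBandCenters = interferentBandCenters,
      interferentBandWidths = interferentBandWidths,
      interferentBandStrengths = interferentBandStrengths,
      interferentMean = interferentMean, interferentSd = interferentSd,
      scatterSlopeSd = scatterSlopeSd, scatterOffsetSd = scatterOffsetSd,
      driftAmplitude = driftAmplitude, noiseSd = noiseSd,
      seed = as.integer(seed))
}

#' Draw reference protein contents from a truncated normal
#'
#' Inverse-CDF sampling of a normal truncated to `[lo, hi]`; values never
#' leave the range, and the draw is deterministic given `seed`.
#'
#' @param n number of samples.
#' @param mean,sd untruncated normal parameters, % mass.
#' @param lo,hi truncation bounds, % mass (`lo < hi`).
#' @param seed integer RNG seed.
#' @return Numeric vector of length `n` within `[lo, hi]`.
#' @examples
#' y <- generateReferenceValues(92, seed = 1)
#' range(y)
#' @export
generateReferenceValues <- function(n, mean = 9.79, sd = 0.7,
                                    lo = 8.43, hi = 11.25, seed = 1L) {
  if (lo >= hi) stop("invalid range: lo must be < hi")
  if (sd <= 0) stop("sd must be > 0")
  withSeed(seed, {
    pLo <- stats::pnorm(lo, mean, sd)
    pHi <- stats::pnorm(hi, mean, sd)
    u <- stats::runif(n, pLo, pHi)
    pmin(hi, pmax(lo, stats::qnorm(u, mean, sd)))
  })
}

# Gaussian band profiles evaluated on the wavelength axis: one row per band.
bandProfiles <- function(centers, widths, wl) {
  t(vapply(seq_along(centers),
           function(k) exp(-(wl - centers[k])^2 / (2 * widths[k]^2)),
           numeric(length(wl))))
}

#' Generate synthetic replicate spectra tied to known protein contents
#'
#' Each measurement (sample i, replicate r) is
#' \deqn{x(\lambda) = a + b \,[\sum_k c_k \varepsilon_k(\lambda) +
#'   d\,\tilde\lambda] + \mathrm{noise},}
#' where the Gaussian bands \eqn{\varepsilon_k} comprise protein-linked bands
#' with \eqn{c_k = \mathrm{strength}_k \times \mathrm{protein}_i} and
#' interferent bands with concentrations independent of protein;
#' \eqn{a \sim N(0, \mathrm{scatterOffsetSd})},
#' \eqn{b \sim N(1, \mathrm{scatterSlopeSd})},
#' \eqn{d \sim N(0, \mathrm{driftAmplitude})} per measurement, and
#' \eqn{\tilde\lambda} is the wavelength scaled to [0, 1]. Deterministic
#' given `config@seed`.
#'
#' @param config a [SyntheticConfig].
#' @param reference protein contents (% mass), length `config@nSamples`.
#' @return A list with elements `spectra` (a [SpectraSet] of
#'   `nSamples * nReplicates` measurements) and `reference` (a data.frame
#'   with columns `sample_id`, `protein`).
#' @examples
#' cfg <- syntheticConfig(nSamples = 4, seed = 1)
#' d <- generateSpectra(cfg, generateReferenceValues(4, seed = 1))
#' dim(intensityMatrix(d$spectra))
#' @export
generateSpectra <- function(config, reference) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  if (length(reference) != config@nSamples)
    stop("reference length (", length(reference),
         ") must equal nSamples (", config@nSamples, ")")
  nS <- config@nSamples; nR <- config@nReplicates
  nMeas <- nS * nR
  wl <- seq(config@wlMin, config@wlMax, length.out = config@nChannels)
  lamTilde <- (wl - config@wlMin) / (config@wlMax - config@wlMin)

  E <- rbind(bandProfiles(config@proteinBandCenters,
                          config@proteinBandWidths, wl),
             if (length(config@interferentBandCenters))
               bandProfiles(config@interferentBandCenters,
                            config@interferentBandWidths, wl))
  nInt <- length(config@interferentBandCenters)

  withSeed(config@seed, {
    interferentConc <- matrix(stats::rnorm(nS * nInt, config@interferentMean,
                                           config@interferentSd), nS, nInt)
    a <- stats::rnorm(nMeas, 0, config@scatterOffsetSd)
    b <- stats::rnorm(nMeas, 1, config@scatterSlopeSd)
    d <- stats::rnorm(nMeas, 0, config@driftAmplitude)
    noise <- matrix(stats::rnorm(nMeas * config@nChannels, 0, config@noiseSd),
                    nMeas, config@nChannels)
  })

  # per-sample band concentrations: protein-linked then interferents
  conc <- cbind(outer(reference, config@proteinBandStrengths),
                if (nInt) interferentConc *
                  rep(config@interferentBandStrengths, each = nS))
  clean <- conc %*% E                      # nSamples x nChannels

  sampleOf <- rep(seq_len(nS), each = nR)
  X <- a + b * (clean[sampleOf, , drop = FALSE] +
                outer(d, lamTilde)) + noise

  ids <- sprintf("S%03d", seq_len(nS))
  spectra <- SpectraSet(X, wl, sampleIds = ids[sampleOf],
                        measurementIds = paste0(ids[sampleOf], "_r",
                                                rep(seq_len(nR), nS)))
  list(spectra = spectra,
       reference = data.frame(sample_id = ids, protein = as.numeric(reference),
                              stringsAsFactors = FALSE))
}

#' Generate a complete synthetic dataset (reference values + spectra)
#'
#' Convenience wrapper drawing the reference protein contents from the
#' configured truncated normal and then the spectra; both draws are
#' deterministic given `config@seed`.
#'
#' @param config a [SyntheticConfig].
#' @return As [generateSpectra()].
#' @export
generateDataset <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  ref <- generateReferenceValues(config@nSamples, config@proteinMean,
                                 config@proteinSd, config@proteinMin,
                                 config@proteinMax,
                                 seed = config@seed + 1000003L)
  generateSpectra(config, ref)
}

#' Channels carrying substantial protein signal
#'
#' Returns the channel indices where the combined protein-linked band
#' response (sum of strength-weighted Gaussian bands) exceeds `threshold`
#' times its maximum — a convenient definition of the generator's "true
#' support" for variable-selection checks.
#'
#' @param config a [SyntheticConfig].
#' @param threshold fraction of the peak response (default 0.5).
#' @return Integer channel indices.
#' @export
trueSupportChannels <- function(config, threshold = 0.5) {
  wl <- seq(config@wlMin, config@wlMax, length.out = config@nChannels)
  prof <- colSums(config@proteinBandStrengths *
                  bandProfiles(config@proteinBandCenters,
                               config@proteinBandWidths, wl))
  which(prof >= threshold * max(prof))
}
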