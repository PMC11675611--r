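# Shared fixtures, all built in code.

# Tiny hand-made SpectraSet: 2 samples, one with 2 replicates.
toySpectra <- function() {
  SpectraSet(rbind(c(1, 2, 3), c(1, 4, 3), c(5, 6, 7)),
             wavelengths = c(940, 1300, 1660),
             sampleIds = c("a", "a", "b"),
             measurementIds = c("a_r1", "a_r2", "b_r1"))
}

# Generator configuration with a single narrow protein band and every
# degradation switched off except small channel noise: the response support
# is a known contiguous channel block (trueSupportChannels at 5% response).
knownSupportConfig <- function(seed) {
  syntheticConfig(seed = seed,
                  proteinBandCenters = 1195, proteinBandWidths = 13,
                  proteinBandStrengths = 0.02,
                  interferentBandCenters = numeric(),
                  interferentBandWidths = numeric(),
                  interferentBandStrengths = numeric(),
                  scatterSlopeSd = 0, scatterOffsetSd = 0,
                  driftAmplitude = 0, noiseSd = 0.001)
}

# Generate, replicate-average, join and split one synthetic dataset.
preparedData <- function(config) {
  d <- generateDataset(config)
  avg <- averageReplicates(d$spectra)
  xy <- joinReference(avg, d$reference)
  part <- concentrationGradientSplit(xy$y)
  list(XCal = xy$X[calibrationIndices(part), , drop = FALSE],
       yCal = xy$y[calibrationIndices(part)],
       XPred = xy$X[predictionIndices(part), , drop = FALSE],
       yPred = xy$y[predictionIndices(part)],
       wavelengths = xy$wavelengths)
}

# One preprocessing + PLSR run on a synthetic dataset, CV-tuned.
recoveryRun <- function(seed, preprocessing, config = syntheticConfig(seed = seed)) {
  data <- preparedData(config)
  pp <- applyPreprocessing(preprocessing, data$XCal, data$XPred,
                           data$wavelengths)
  nc <- selectNComponents(pp$calibration, data$yCal, 20, 5, seed)
  m <- plsrFit(pp$calibration, data$yCal, nc)
  evaluateRun(m, pp$calibration, data$yCal, pp$prediction, data$yPred,
              info = list(preprocessing = preprocessing, model = "plsr",
                          seed = seed))
}
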