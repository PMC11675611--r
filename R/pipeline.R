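#' Build an experiment configuration
#'
#' Describes a full calibration experiment: the data source (a
#' [SyntheticConfig], or a [SpectraSet] plus reference table), the
#' preprocessing/model/selection grids, the split ratio and the tuning
#' settings. All randomness downstream derives from `seed`.
#'
#' @param synthetic a [SyntheticConfig] used when no measured data are
#'   supplied.
#' @param spectra optional [SpectraSet] of measured spectra.
#' @param reference optional reference data.frame (`sample_id`, `protein`);
#'   required with `spectra`.
#' @param preprocessings preprocessing variant names for the
#'   full-wavelength grid.
#' @param models model names among `"plsr"`, `"svm-linear"`, `"svm-rbf"`,
#'   `"elm"`.
#' @param selectionPreprocessings preprocessing variants entering the
#'   feature-selection grid.
#' @param selectionMethods `"SPA"`, `"UVE"` or both.
#' @param ratioCal,ratioPred concentration-gradient split ratio (default
#'   3:1).
#' @param maxComponents PLSR component cap (default 20).
#' @param spaMaxVars largest SPA subset (default 20).
#' @param uveNoiseScale UVE artificial-noise amplitude (default 1e-10).
#' @param neuronCandidates ELM hidden-layer candidates (default 10:60).
#' @param svrEpsilon SVR tube half-width (default 0.01).
#' @param kFolds CV folds used by every tuner (default 5).
#' @param seed master seed.
#' @return A named list of class `"ExperimentConfig"`.
#' @export
experimentConfig <- function(synthetic = syntheticConfig(),
                             spectra = NULL, reference = NULL,
                             preprocessings = preprocessingNames(),
                             models = c("plsr", "svm-linear", "elm"),
                             selectionPreprocessings = c("X", "1D+MSC", "1D+SNV"),
                             selectionMethods = c("SPA", "UVE"),
                             ratioCal = 3L, ratioPred = 1L,
                             maxComponents = 20L, spaMaxVars = 20L,
                             uveNoiseScale = 1e-10,
                             neuronCandidates = 10:60, svrEpsilon = 0.01,
                             kFolds = 5L, seed = 1L) {
  known <- c("plsr", "svm-linear", "svm-rbf", "elm")
  if (!all(models %in% known))
    stop("unknown model(s): ", paste(setdiff(models, known), collapse = ", "))
  if (!all(preprocessings %in% preprocessingNames()))
    stop("unknown preprocessing(s): ",
         paste(setdiff(preprocessings, preprocessingNames()), collapse = ", "))
  if (!all(selectionMethods %in% c("SPA", "UVE")))
    stop("selection methods must be 'SPA' and/or 'UVE'")
  if (!is.null(spectra) && is.null(reference))
    stop("measured spectra need a reference table")
  structure(list(synthetic = synthetic, spectra = spectra,
                 reference = reference, preprocessings = preprocessings,
                 models = models,
                 selectionPreprocessings = selectionPreprocessings,
                 selectionMethods = selectionMethods,
                 ratioCal = as.integer(ratioCal),
                 ratioPred = as.integer(ratioPred),
                 maxComponents = as.integer(maxComponents),
                 spaMaxVars = as.integer(spaMaxVars),
                 uveNoiseScale = uveNoiseScale,
                 neuronCandidates = as.integer(neuronCandidates),
                 svrEpsilon = svrEpsilon, kFolds = as.integer(kFolds),
                 seed = as.integer(seed)),
            class = "ExperimentConfig")
}

# Generate/load, replicate-average, join and split the dataset for a config.
prepareDataset <- function(config) {
  if (!is.null(config$spectra)) {
    spectra <- config$spectra
    reference <- config$reference
  } else {
    cfg <- config$synthetic
    cfg@seed <- config$seed
    d <- generateDataset(cfg)
    spectra <- d$spectra
    reference <- d$reference
  }
  avg <- averageReplicates(spectra)
  xy <- joinReference(avg, reference)
  part <- concentrationGradientSplit(xy$y, config$ratioCal, config$ratioPred)
  list(XCal = xy$X[calibrationIndices(part), , drop = FALSE],
       yCal = xy$y[calibrationIndices(part)],
       XPred = xy$X[predictionIndices(part), , drop = FALSE],
       yPred = xy$y[predictionIndices(part)],
       wavelengths = xy$wavelengths, partition = part)
}

# Tune + fit one model on preprocessed data; returns list(model, hyper label).
fitTunedModel <- function(model, XCal, yCal, config) {
  switch(model,
    "plsr" = {
      nc <- selectNComponents(XCal, yCal, config$maxComponents,
                              config$kFolds, config$seed)
      list(model = plsrFit(XCal, yCal, nc),
           hyperparameter = sprintf("nComponents=%d", nc))
    },
    "svm-linear" = {
      g <- svrGridSearch(XCal, yCal, "linear", config$kFolds, config$seed,
                         config$svrEpsilon)
      list(model = g$model, hyperparameter = sprintf("c=%.4f", g$cost))
    },
    "svm-rbf" = {
      g <- svrGridSearch(XCal, yCal, "rbf", config$kFolds, config$seed,
                         config$svrEpsilon)
      list(model = g$model,
           hyperparameter = sprintf("c=%.4f,g=%.4f", g$cost, g$gamma))
    },
    "elm" = {
      L <- selectNNeurons(XCal, yCal, config$neuronCandidates,
                          config$kFolds, config$seed)
      list(model = elmFit(XCal, yCal, L, seed = config$seed),
           hyperparameter = sprintf("neurons=%d", L))
    },
    stop("unknown model '", model, "'"))
}

failedRow <- function(preprocessing, selection, model, seed, message) {
  data.frame(preprocessing = preprocessing, selection = selection,
             model = model, nBands = NA_integer_,
             hyperparameter = NA_character_, seed = seed,
             nCal = NA_integer_, nPred = NA_integer_,
             Rc = NA_real_, RMSEc = NA_real_, Rp = NA_real_,
             RMSEp = NA_real_, RPD = NA_real_, sdPrediction = NA_real_,
             status = "failed", message = message,
             stringsAsFactors = FALSE)
}

#' Run the full-wavelength preprocessing x model grid
#'
#' One evaluation row per (preprocessing, model) combination, each tuned by
#' cross-validation on the calibration set only. A failing grid cell is
#' recorded as a failed row and the run continues.
#'
#' @param config an [experimentConfig()].
#' @return A data.frame with one row per grid cell (metrics as in
#'   [reportTable()], plus `status`/`message`).
#' @export
runFullWavelengthGrid <- function(config) {
  data <- prepareDataset(config)
  rows <- list()
  for (prep in config$preprocessings) {
    pp <- tryCatch(applyPreprocessing(prep, data$XCal, data$XPred,
                                      data$wavelengths),
                   error = function(e) e)
    for (model in config$models) {
      rows[[length(rows) + 1L]] <- tryCatch({
        if (inherits(pp, "error")) stop(conditionMessage(pp))
        tuned <- fitTunedModel(model, pp$calibration, data$yCal, config)
        rep <- evaluateRun(tuned$model, pp$calibration, data$yCal,
                           pp$prediction, data$yPred,
                           info = list(preprocessing = prep,
                                       selection = "none", model = model,
                                       nBands = ncol(pp$calibration),
                                       hyperparameter = tuned$hyperparameter,
                                       seed = config$seed))
        cbind(reportTable(rep), status = "ok", message = "",
              stringsAsFactors = FALSE)
      }, error = function(e)
        failedRow(prep, "none", model, config$seed, conditionMessage(e)))
    }
  }
  do.call(rbind, rows)
}

#' Run the feature-selection x PLSR grid
#'
#' For each configured preprocessing variant, SPA and/or UVE select
#' wavelengths on the calibration set; a PLSR model is then tuned and
#' evaluated on the selected channels. UVE's internal latent-variable count
#' is chosen beforehand by CV on the real channels.
#'
#' @param config an [experimentConfig()].
#' @return A list with `table` (data.frame, one row per preprocessing x
#'   selector, including `nBands` and `hMax`) and `selections` (named list
#'   of [FeatureSelectionResult]s).
#' @export
runFeatureSelectionGrid <- function(config) {
  data <- prepareDataset(config)
  rows <- list(); selections <- list()
  for (prep in config$selectionPreprocessings) {
    pp <- tryCatch(applyPreprocessing(prep, data$XCal, data$XPred,
                                      data$wavelengths),
                   error = function(e) e)
    for (method in config$selectionMethods) {
      key <- paste(prep, method, sep = "|")
      rows[[key]] <- tryCatch({
        if (inherits(pp, "error")) stop(conditionMessage(pp))
        sel <- if (method == "SPA") {
          spaSelect(pp$calibration, data$yCal, config$spaMaxVars,
                    config$seed, config$kFolds,
                    wavelengths = data$wavelengths)
        } else {
          nLv <- selectNComponents(pp$calibration, data$yCal,
                                   config$maxComponents, config$kFolds,
                                   config$seed)
          uveSelect(pp$calibration, data$yCal, nLv,
                    config$uveNoiseScale, config$seed,
                    wavelengths = data$wavelengths)
        }
        selections[[key]] <- sel
        idx <- selectedIndices(sel)
        if (!length(idx)) stop("empty selection")
        XcSel <- pp$calibration[, idx, drop = FALSE]
        XpSel <- pp$prediction[, idx, drop = FALSE]
        nc <- selectNComponents(XcSel, data$yCal,
                                min(config$maxComponents, length(idx)),
                                config$kFolds, config$seed)
        m <- plsrFit(XcSel, data$yCal, nc)
        rep <- evaluateRun(m, XcSel, data$yCal, XpSel, data$yPred,
                           info = list(preprocessing = prep,
                                       selection = method, model = "plsr",
                                       nBands = length(idx),
                                       hyperparameter =
                                         sprintf("nComponents=%d", nc),
                                       seed = config$seed))
        tab <- cbind(reportTable(rep), status = "ok", message = "",
                     stringsAsFactors = FALSE)
        tab$hMax <- if (method == "UVE") hMax(sel) else NA_real_
        tab
      }, error = function(e) {
        r <- failedRow(prep, method, "plsr", config$seed, conditionMessage(e))
        r$hMax <- NA_real_
        r
      })
    }
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       selections = selections)
}

#' Compare wavelength selections across methods
#'
#' Pairwise intersection/union counts and Jaccard overlap for a set of
#' [FeatureSelectionResult]s on the same wavelength axis, plus the
#' wavelengths unique to each result.
#'
#' @param results named list of [FeatureSelectionResult]s (>= 2).
#' @return A list with `pairwise` (data.frame) and `uniqueTo` (named list
#'   of wavelength vectors, or indices if no axis was recorded).
#' @export
compareSelectedWavelengths <- function(results) {
  if (length(results) < 2)
    stop("need at least two selection results")
  axes <- lapply(results, function(r) r@wavelengthAxis)
  if (length(unique(vapply(axes, length, integer(1)))) > 1 ||
      (length(axes[[1]]) &&
       !all(vapply(axes[-1], function(a) isTRUE(all.equal(a, axes[[1]])),
                   logical(1)))))
    stop("selection results are on different wavelength axes")
  nm <- names(results) %||% paste0("result", seq_along(results))
  sets <- lapply(results, selectedIndices)
  combs <- utils::combn(seq_along(sets), 2)
  pairwise <- do.call(rbind, apply(combs, 2, function(ij) {
    a <- sets[[ij[1]]]; b <- sets[[ij[2]]]
    data.frame(a = nm[ij[1]], b = nm[ij[2]],
               intersection = length(intersect(a, b)),
               union = length(union(a, b)),
               jaccard = if (length(union(a, b)) == 0) NA_real_
                         else length(intersect(a, b)) / length(union(a, b)),
               stringsAsFactors = FALSE)
  }, simplify = FALSE))
  others <- function(i) unique(unlist(sets[-i]))
  uniqueTo <- lapply(seq_along(sets), function(i) {
    u <- sort(setdiff(sets[[i]], others(i)))
    if (length(axes[[i]])) axes[[i]][u] else u
  })
  names(uniqueTo) <- nm
  list(pairwise = pairwise, uniqueTo = uniqueTo)
}

#' Run the complete experiment
#'
#' Full-wavelength grid, feature-selection grid and the SPA/UVE wavelength
#' comparison, all driven by one configuration and seed. Output contains no
#' timestamps, so two runs with the same configuration are identical.
#'
#' @param config an [experimentConfig()].
#' @return A list with `fullGrid`, `selectionGrid`, `comparison` and `seed`.
#' @export
runExperiment <- function(config) {
  full <- runFullWavelengthGrid(config)
  selGrid <- runFeatureSelectionGrid(config)
  comparison <- if (length(selGrid$selections) >= 2)
    compareSelectedWavelengths(selGrid$selections) else NULL
  list(fullGrid = full, selectionGrid = selGrid$table,
       comparison = comparison, selections = selGrid$selections,
       seed = config$seed)
}
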