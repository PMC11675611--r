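#' Correlation metric R between reference and predicted values
#'
#' The workflow's printed convention is R = 1 - SSres/SStot (algebraically a
#' coefficient of determination); `method = "pearson"` gives the
#' conventional Pearson correlation for comparison.
#'
#' @param yActual,yPredicted numeric vectors of equal length >= 2;
#'   `yActual` must not be constant.
#' @param method `"printed"` (default) or `"pearson"`.
#' @return Scalar R.
#' @examples
#' rMetric(c(1, 2, 3), c(1, 2, 4))  # 0.5
#' @export
rMetric <- function(yActual, yPredicted, method = c("printed", "pearson")) {
  method <- match.arg(method)
  if (length(yActual) != length(yPredicted) || length(yActual) < 2)
    stop("need two equal-length vectors with >= 2 values")
  if (stats::sd(yActual) == 0) stop("degenerate: yActual is constant")
  if (method == "pearson") return(stats::cor(yActual, yPredicted))
  1 - sum((yActual - yPredicted)^2) / sum((yActual - mean(yActual))^2)
}

#' Root mean square error with an N-1 denominator
#'
#' The workflow's printed convention divides the residual sum of squares by
#' N-1; `denominator = "n"` gives the conventional mean-square version.
#'
#' @param yActual,yPredicted numeric vectors of equal length >= 2.
#' @param denominator `"n-1"` (default) or `"n"`.
#' @return Scalar RMSE (same units as y).
#' @examples
#' rmseMetric(rep(0, 4), c(0.3, -0.3, 0.3, -0.3))  # sqrt(0.36 / 3)
#' @export
rmseMetric <- function(yActual, yPredicted, denominator = c("n-1", "n")) {
  denominator <- match.arg(denominator)
  n <- length(yActual)
  if (length(yPredicted) != n || n < 2)
    stop("need two equal-length vectors with >= 2 values")
  d <- if (denominator == "n-1") n - 1 else n
  sqrt(sum((yActual - yPredicted)^2) / d)
}

#' Residual predictive deviation (RPD)
#'
#' Ratio of the prediction-set reference SD to the prediction RMSE.
#'
#' @param sdPrediction sample SD of the prediction-set reference values.
#' @param rmseP prediction RMSE (> 0).
#' @return Scalar RPD.
#' @examples
#' rpd(0.7, 0.3)  # 2.33..., reported as 2.3
#' @export
rpd <- function(sdPrediction, rmseP) {
  if (rmseP == 0) stop("infinite RPD: rmseP is zero")
  sdPrediction / rmseP
}

#' Interpretation band for an RPD value
#'
#' 1.5-2: the model discriminates low from high values; 2-2.5: coarse
#' quantitative predictions are possible; 2.5-3: good prediction accuracy;
#' >= 3: excellent.
#'
#' @param x RPD value.
#' @return Character label.
#' @export
rpdBand <- function(x) {
  if (!is.finite(x)) return("degenerate (zero prediction error)")
  if (x < 1.5) "insufficient for prediction"
  else if (x < 2) "discriminates low from high values"
  else if (x < 2.5) "coarse quantitative predictions possible"
  else if (x < 3) "good prediction accuracy"
  else "excellent prediction accuracy"
}

#' Concentration-gradient 3:1 calibration/prediction split
#'
#' Samples are sorted by reference value (ties by original index) and cut
#' into consecutive blocks of `ratioCal + ratioPred`; in each full block the
#' samples at sorted positions 2..(1 + ratioPred) go to the prediction set
#' and the rest to calibration, and remainder samples go to calibration.
#' Because block positions 1 and ratioCal + ratioPred always stay in
#' calibration, the prediction-set reference range is contained in the
#' calibration range. Fully deterministic.
#'
#' @param reference numeric reference values, length
#'   `>= ratioCal + ratioPred`.
#' @param ratioCal,ratioPred block counts for the two sets (default 3:1;
#'   `ratioCal >= 2` so the containment property holds).
#' @return A [Partition].
#' @examples
#' p <- concentrationGradientSplit(generateReferenceValues(92, seed = 1))
#' length(calibrationIndices(p))  # 69
#' @export
concentrationGradientSplit <- function(reference, ratioCal = 3L,
                                       ratioPred = 1L) {
  ratioCal <- as.integer(ratioCal); ratioPred <- as.integer(ratioPred)
  if (ratioPred < 1L || ratioCal < 2L)
    stop("need ratioPred >= 1 and ratioCal >= 2")
  n <- length(reference)
  bs <- ratioCal + ratioPred
  if (n < bs) stop("need at least ratioCal + ratioPred samples")
  ord <- order(reference, seq_len(n))
  nFull <- n %/% bs
  predPos <- as.vector(outer(2:(1L + ratioPred), (seq_len(nFull) - 1L) * bs,
                             "+"))
  pred <- sort(ord[predPos])
  new("Partition", calibration = setdiff(seq_len(n), pred),
      prediction = pred)
}

#' Evaluate a fitted model on a calibration/prediction split
#'
#' Computes R and RMSE on both sets (printed conventions: R = 1 -
#' SSres/SStot, RMSE with N-1 denominator), the sample SD of the
#' prediction-set reference values, and RPD = SD / RMSEP. A model that
#' predicts the prediction set exactly yields `rpd = Inf` with a warning.
#'
#' @param model a fitted [PLSRModel], [SVRModel] or [ELMModel] (anything
#'   with a `predict` method).
#' @param XCal,yCal,XPred,yPred the two aligned data blocks.
#' @param info optional named list of run metadata (preprocessing, model
#'   name, hyperparameters, seed, ...) stored in the report.
#' @return An [EvaluationReport].
#' @export
evaluateRun <- function(model, XCal, yCal, XPred, yPred, info = list()) {
  predCal <- predict(model, XCal)
  predPred <- predict(model, XPred)
  rmseP <- rmseMetric(yPred, predPred)
  sdP <- stats::sd(yPred)
  rpdVal <- if (rmseP == 0) {
    warning("zero prediction RMSE; reporting infinite RPD")
    Inf
  } else sdP / rmseP
  new("EvaluationReport",
      rC = rMetric(yCal, predCal), rmseC = rmseMetric(yCal, predCal),
      rP = rMetric(yPred, predPred), rmseP = rmseP,
      rpd = rpdVal, sdPrediction = sdP,
      nCal = length(yCal), nPred = length(yPred), info = info)
}

#' Tabulate evaluation reports
#'
#' Collects a list of [EvaluationReport]s into a data.frame mirroring the
#' standard calibration-table column order (preprocessing, number of
#' bands/components, R_c, RMSE_c, R_p, RMSE_p, RPD), with raw metric values.
#'
#' @param reports a list of [EvaluationReport]s (or a single one).
#' @return A data.frame, one row per report.
#' @export
reportTable <- function(reports) {
  if (is(reports, "EvaluationReport")) reports <- list(reports)
  rows <- lapply(reports, function(r) {
    meta <- r@info
    data.frame(
      preprocessing = meta$preprocessing %||% NA_character_,
      selection = meta$selection %||% "none",
      model = meta$model %||% NA_character_,
      nBands = meta$nBands %||% NA_integer_,
      hyperparameter = meta$hyperparameter %||% NA_character_,
      seed = meta$seed %||% NA_integer_,
      nCal = r@nCal, nPred = r@nPred,
      Rc = r@rC, RMSEc = r@rmseC, Rp = r@rP, RMSEp = r@rmseP,
      RPD = r@rpd, sdPrediction = r@sdPrediction,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round a report table for display
#'
#' R to two decimals, RMSE and RPD to two decimals, mirroring the usual
#' calibration-table printing; raw values stay available in the unrounded
#' table.
#'
#' @param tab a data.frame from [reportTable()].
#' @return The table with rounded metric columns.
#' @export
formatReportTable <- function(tab) {
  for (cl in intersect(c("Rc", "RMSEc", "Rp", "RMSEp", "RPD"), colnames(tab)))
    tab[[cl]] <- round(tab[[cl]], 2)
  tab
}
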