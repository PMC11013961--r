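#' Build a count-record table
#'
#' One row per test image: the observed tassel count and the predicted
#' count. All evaluation metrics operate on this table.
#'
#' @param imageId character vector of image identifiers.
#' @param observed non-negative integer observed counts.
#' @param predicted non-negative real predicted counts.
#' @return data.frame with columns image_id, observed, predicted.
#' @export
countRecords <- function(imageId, observed, predicted) {
  stopifnot(length(imageId) == length(observed),
            length(observed) == length(predicted))
  if (length(observed) && (min(observed) < 0 ||
                           any(observed != round(observed))))
    stop("observed counts must be non-negative integers")
  if (length(predicted) && min(predicted) < 0)
    stop("predicted counts must be non-negative")
  data.frame(image_id = as.character(imageId),
             observed = as.numeric(observed),
             predicted = as.numeric(predicted))
}

checkRecords <- function(records, minN = 1L) {
  stopifnot(is.data.frame(records),
            all(c("observed", "predicted") %in% names(records)))
  if (nrow(records) < minN)
    stop("need at least ", minN, " count record(s)")
  invisible(records)
}

#' Mean absolute error of per-image counts
#'
#' @param records count records (see [countRecords()]).
#' @return mean of |observed - predicted|.
#' @export
countMae <- function(records) {
  checkRecords(records)
  mean(abs(records$observed - records$predicted))
}

#' Normalized mean square prediction error (NMSPE)
#'
#' Mean over test images of (observed - predicted)^2 / predicted, a
#' Chi-squared-like goodness-of-fit statistic for count predictions. The
#' denominator is floored (default 0.5 counts) to guard against zero
#' predictions.
#'
#' @param records count records.
#' @param floor lower bound applied to the denominator.
#' @return non-negative real; 0 iff all predictions are exact.
#' @export
nmspe <- function(records, floor = 0.5) {
  checkRecords(records)
  mean((records$observed - records$predicted)^2 /
         pmax(records$predicted, floor))
}

#' Predictive deviance (PD)
#'
#' Poisson-deviance-style statistic
#' 2 sum\[Tk log(Tk / That_k) - (Tk - That_k)\] over test images, with the
#' leading term set to 0 when the observed count Tk is 0. Predictions are
#' floored (default 0.5) before entering the logarithm and the linear term.
#'
#' @param records count records.
#' @param floor lower bound applied to predictions.
#' @return non-negative real; 0 iff observed = predicted (above the floor)
#'   for every record.
#' @export
predictiveDeviance <- function(records, floor = 0.5) {
  checkRecords(records)
  obs <- records$observed
  pred <- pmax(records$predicted, floor)
  lead <- ifelse(obs == 0, 0, obs * log(obs / pred))
  2 * sum(lead - (obs - pred))
}

#' Spearman rank correlation of observed versus predicted counts
#'
#' Average ranks are used for ties.
#'
#' @param records count records with at least 2 rows.
#' @return correlation in \[-1, 1\].
#' @export
spearmanCount <- function(records) {
  checkRecords(records, 2L)
  if (stats::sd(records$observed) == 0 || stats::sd(records$predicted) == 0)
    stopDegenerate("correlation undefined: zero variance in counts")
  stats::cor(records$observed, records$predicted, method = "spearman")
}

#' Squared Pearson correlation (r^2) of observed versus predicted counts
#'
#' @param records count records with at least 2 rows and non-zero variance
#'   on both sides.
#' @return r-squared in \[0, 1\].
#' @export
rSquaredCount <- function(records) {
  checkRecords(records, 2L)
  if (stats::sd(records$observed) == 0 || stats::sd(records$predicted) == 0)
    stopDegenerate("correlation undefined: zero variance in counts")
  stats::cor(records$observed, records$predicted)^2
}

#' All count-accuracy metrics in one report
#'
#' @param records count records.
#' @param floor denominator/log floor for NMSPE and PD.
#' @return named list: mae, nmspe, pd, spearman, r_squared, n.
#' @export
countMetrics <- function(records, floor = 0.5) {
  checkRecords(records, 2L)
  list(mae = countMae(records), nmspe = nmspe(records, floor),
       pd = predictiveDeviance(records, floor),
       spearman = spearmanCount(records),
       r_squared = rSquaredCount(records), n = nrow(records))
}

#' Write a metrics report to JSON
#'
#' @param metrics output of [countMetrics()].
#' @param path destination JSON path.
#' @return the path, invisibly.
#' @export
writeMetricsReport <- function(metrics, path) {
  jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Count tassel candidates by connected components
#'
#' A detector-free counter standing in for a trained object detector: the
#' image is passed through the two-step filter, the surviving mask is
#' labeled with 8-connected components, and components with at least
#' `minArea` pixels are counted; their bounding boxes are returned.
#'
#' @param img an [RgbImage-class].
#' @param exgThreshold step-1 (ExG) threshold.
#' @param tasselThreshold step-2 (tassel-index) threshold.
#' @param minArea minimum component area in pixels (default 12, a plausible
#'   tassel footprint at plot-crop resolution).
#' @param variant tassel-index variant.
#' @return list with `count` (integer) and `boxes` (a [BoxAnnotation-class]
#'   of surviving components).
#' @export
baselineComponentCounter <- function(img, exgThreshold = 131,
                                     tasselThreshold = 90, minArea = 12L,
                                     variant = "prose") {
  fr <- twoStepFilter(img, exgThreshold, tasselThreshold, variant)
  keep <- fr@step1Mask@keep & fr@step2Mask@keep
  countComponents(keep, minArea, img@imageId)
}

countComponents <- function(keep, minArea, imageId = "image") {
  lab <- labelComponents8(keep)
  if (max(lab) == 0L)
    return(list(count = 0L,
                boxes = new("BoxAnnotation", imageId = imageId,
                            boxes = cbind(rowMin = numeric(),
                                          colMin = numeric(),
                                          height = numeric(),
                                          width = numeric()))))
  areas <- tabulate(lab[lab > 0L], nbins = max(lab))
  ok <- which(areas >= minArea)
  boxes <- t(vapply(ok, function(l) {
    w <- which(lab == l, arr.ind = TRUE)
    c(rowMin = min(w[, 1]) - 1, colMin = min(w[, 2]) - 1,
      height = diff(range(w[, 1])) + 1, width = diff(range(w[, 2])) + 1)
  }, numeric(4)))
  if (length(ok) == 0L)
    boxes <- cbind(rowMin = numeric(), colMin = numeric(),
                   height = numeric(), width = numeric())
  list(count = length(ok),
       boxes = new("BoxAnnotation", imageId = imageId, boxes = boxes))
}

#' Baseline counter as a sweep-ready function
#'
#' Returns a counter closure `function(img, tasselThreshold)` suitable for
#' [thresholdSweep()]. The step-1 ExG mask and the rescaled tassel-index
#' map of each image are computed once and memoized (keyed by imageId), so
#' sweeping 256 thresholds only re-runs the cheap mask-and-label step.
#'
#' @inheritParams baselineComponentCounter
#' @return function(img, tasselThreshold) -> non-negative count.
#' @export
makeBaselineCounter <- function(exgThreshold = 131, minArea = 12L,
                                variant = "prose") {
  cache <- new.env(parent = emptyenv())
  function(img, tasselThreshold) {
    key <- img@imageId
    if (is.null(cache[[key]])) {
      nc <- normalizeChannels(img)
      cache[[key]] <- list(
        step1 = rescaleIndex(excessGreen(nc))@values >= exgThreshold,
        tassel = rescaleIndex(tasselIndex(nc, variant))@values)
    }
    e <- cache[[key]]
    keep <- e$step1 & (e$tassel >= tasselThreshold)
    countComponents(keep, minArea, key)$count
  }
}

#' r-squared sweep over step-2 filter thresholds
#'
#' For every threshold t, each test image is filtered at step-2 threshold t
#' (the step-1 ExG threshold is held fixed inside `counter`), the counter is
#' run, and the r-squared of predicted versus observed counts is recorded.
#' Thresholds where the predictions are constant (for instance when
#' everything has been filtered away) are recorded as r-squared 0 with a
#' degenerate flag so curves remain plottable.
#'
#' @param counter a function(img, tasselThreshold) returning a count, e.g.
#'   from [makeBaselineCounter()], or any user-supplied detector wrapper.
#' @param testImages list of at least 2 [RgbImage-class] objects.
#' @param truth numeric observed counts aligned with `testImages`
#'   (non-constant).
#' @param thresholds integer thresholds to sweep (default 0:255).
#' @return a [SweepResult-class]; ties in the argmax resolve to the lowest
#'   threshold.
#' @export
thresholdSweep <- function(counter, testImages, truth, thresholds = 0:255) {
  stopifnot(is.function(counter), length(testImages) >= 2L,
            length(testImages) == length(truth))
  if (stats::sd(truth) == 0)
    stopDegenerate("threshold sweep needs non-constant true counts")
  nT <- length(thresholds)
  r2 <- numeric(nT)
  degen <- logical(nT)
  for (i in seq_len(nT)) {
    preds <- vapply(testImages,
                    function(im) counter(im, thresholds[i]), numeric(1))
    if (stats::sd(preds) == 0) {
      r2[i] <- 0
      degen[i] <- TRUE
    } else {
      r2[i] <- stats::cor(truth, preds)^2
    }
  }
  best <- which.max(r2)  # which.max returns the first (lowest) maximum
  new("SweepResult", thresholds = as.integer(thresholds), rSquared = r2,
      degenerate = degen, bestThreshold = as.integer(thresholds[best]),
      bestRSquared = r2[best])
}

#' Write a sweep result to JSON
#'
#' @param sweep a [SweepResult-class].
#' @param path destination JSON path.
#' @return the path, invisibly.
#' @export
writeSweepResult <- function(sweep, path) {
  jsonlite::write_json(
    list(thresholds = sweep@thresholds, r_squared = sweep@rSquared,
         degenerate = sweep@degenerate,
         best_threshold = sweep@bestThreshold,
         best_r_squared = sweep@bestRSquared),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
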