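#' @rdname RgbImage-class
#' @param x an object.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname RgbImage-class
#' @export
setGeneric("imageId", function(x) standardGeneric("imageId"))

#' @rdname IndexMap-class
#' @param x an object.
#' @export
setGeneric("indexValues", function(x) standardGeneric("indexValues"))

#' @rdname IndexMap-class
#' @export
setGeneric("indexName", function(x) standardGeneric("indexName"))

#' @rdname BinaryMask-class
#' @param x an object.
#' @export
setGeneric("maskKeep", function(x) standardGeneric("maskKeep"))

#' @rdname DensityMap-class
#' @param x an object.
#' @export
setGeneric("densityValues", function(x) standardGeneric("densityValues"))

setMethod("pixels", "RgbImage", function(x) x@pixels)
setMethod("imageId", "RgbImage", function(x) x@imageId)
setMethod("imageId", "PointAnnotation", function(x) x@imageId)
setMethod("imageId", "BoxAnnotation", function(x) x@imageId)
setMethod("indexValues", "IndexMap", function(x) x@values)
setMethod("indexName", "IndexMap", function(x) x@indexName)
setMethod("indexValues", "RescaledIndexMap", function(x) x@values)
setMethod("indexName", "RescaledIndexMap", function(x) x@indexName)
setMethod("maskKeep", "BinaryMask", function(x) x@keep)
setMethod("densityValues", "DensityMap", function(x) x@values)

setMethod("show", "RgbImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("RgbImage '%s': %d x %d x 3 (8-bit)\n",
              object@imageId, d[1], d[2]))
})

showIndexMap <- function(object) {
  cat(sprintf("%s '%s'%s: %d x %d, range [%g, %g], values [%.3f, %.3f]\n",
              class(object), object@indexName,
              if (object@indexName == "tassel")
                sprintf(" (%s)", object@variant) else "",
              nrow(object@values), ncol(object@values),
              object@rangeMin, object@rangeMax,
              min(object@values), max(object@values)))
}
setMethod("show", "IndexMap", showIndexMap)
setMethod("show", "RescaledIndexMap", showIndexMap)

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask: %d x %d, %.1f%% kept\n",
              nrow(object@keep), ncol(object@keep),
              100 * mean(object@keep)))
})

setMethod("show", "FilterResult", function(object) {
  cat(sprintf(paste0("FilterResult (exg threshold %g, tassel threshold %g)\n",
                     "  step 1 keeps %.1f%%, step 2 keeps %.1f%%, ",
                     "combined %.1f%%\n"),
              object@thresholds["exg"], object@thresholds["tassel"],
              100 * mean(object@step1Mask@keep),
              100 * mean(object@step2Mask@keep),
              100 * mean(object@step1Mask@keep & object@step2Mask@keep)))
})

setMethod("show", "PointAnnotation", function(object) {
  cat(sprintf("PointAnnotation '%s': %d points\n",
              object@imageId, nrow(object@points)))
})

setMethod("show", "BoxAnnotation", function(object) {
  cat(sprintf("BoxAnnotation '%s': %d boxes\n",
              object@imageId, nrow(object@boxes)))
})

setMethod("show", "EliminationCurve", function(object) {
  cat(sprintf("EliminationCurve for index '%s' (%s)\n", object@indexName,
              object@variant))
  for (nm in names(object@perClass))
    cat(sprintf("  %-8s n=%d\n", nm, object@sampleSizes[[nm]]))
})

setMethod("show", "DensityMap", function(object) {
  cat(sprintf("DensityMap: %d x %d, bandwidth %g px, mass %.4f (%d points)\n",
              nrow(object@values), ncol(object@values), object@bandwidth,
              sum(object@values), object@sourcePoints))
})

setMethod("show", "TrainingPatchSet", function(object) {
  cat(sprintf("TrainingPatchSet: %d patches of %d x %d, targets [%.3f, %.3f]\n",
              nrow(object@patches), object@patchSize, object@patchSize,
              if (nrow(object@patches)) min(object@targets) else NA,
              if (nrow(object@patches)) max(object@targets) else NA))
})

setMethod("show", "CounterConfig", function(object) {
  cat(sprintf(paste0("CounterConfig: patch %d, stride %d, bandwidth %g, ",
                     "lr %g, epochs <= %d (patience %d), batch %d, ",
                     "widths %s, dropout %g, seed %d\n"),
              object@patchSize, object@stride, object@bandwidth,
              object@learningRate, object@maxEpochs, object@patience,
              object@batchSize, paste(object@convWidths, collapse = "/"),
              object@dropout, object@seed))
})

setMethod("show", "CounterModel", function(object) {
  cat(sprintf("CounterModel: %d conv blocks (%s), best epoch %d, val L1 %.4f\n",
              length(object@params$blocks),
              paste(object@config@convWidths, collapse = "/"),
              object@bestEpoch,
              object@trainLog$val_loss[object@bestEpoch]))
})

setMethod("show", "SyntheticScene", function(object) {
  cat(sprintf("SyntheticScene '%s': %d x %d, %d tassels\n",
              object@image@imageId, nrow(object@classMap),
              ncol(object@classMap), nrow(object@points@points)))
})

setMethod("show", "SweepResult", function(object) {
  cat(sprintf("SweepResult over %d thresholds: best r^2 %.4f at threshold %d\n",
              length(object@thresholds), object@bestRSquared,
              object@bestThreshold))
})
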