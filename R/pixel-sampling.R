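#' Marker colors of the pixel-sampling scheme
#'
#' Pure marker colors used in hand-marked sampling images: soil blue
#' (0,0,255), shadow green (0,255,0), foliage red (255,0,0), tassel yellow
#' (255,255,0).
#'
#' @return named list of length-3 integer vectors.
#' @export
markerColors <- function() {
  list(soil = c(0L, 0L, 255L), shadow = c(0L, 255L, 0L),
       foliage = c(255L, 0L, 0L), tassel = c(255L, 255L, 0L))
}

#' Extract labeled sample pixels from a marker image
#'
#' Scans a color-marked copy of an image for the four pure marker colors and
#' records the coordinates of every matching pixel, grouped by class. The
#' index formulas are later applied to the corresponding pixels of the
#' unmarked original. Matching is exact by default; a per-channel tolerance
#' can be allowed for hand-marked data, in which case a coordinate matching
#' two classes is rejected as an annotation error.
#'
#' @param marked the marked [RgbImage-class].
#' @param original the unmarked [RgbImage-class] of identical shape.
#' @param tolerance per-channel absolute tolerance (default 0, exact match).
#' @return named list of [PixelClassSample-class] objects (one per class,
#'   possibly with zero coordinates).
#' @export
extractSamples <- function(marked, original, tolerance = 0) {
  stopifnot(is(marked, "RgbImage"), is(original, "RgbImage"))
  if (!identical(dim(marked@pixels), dim(original@pixels)))
    stop("marked and original images must have identical shape")
  mk <- markerColors()
  p <- marked@pixels
  hits <- lapply(mk, function(col) {
    abs(p[, , 1] - col[1]) <= tolerance &
      abs(p[, , 2] - col[2]) <= tolerance &
      abs(p[, , 3] - col[3]) <= tolerance
  })
  overlap <- Reduce(`+`, hits)
  if (any(overlap > 1))
    stop("overlapping class marks at ", sum(overlap > 1), " coordinate(s)")
  out <- lapply(names(mk), function(cls) {
    w <- which(hits[[cls]], arr.ind = TRUE)
    coords <- cbind(row = w[, 1] - 1L, col = w[, 2] - 1L)
    new("PixelClassSample", imageId = original@imageId, classLabel = cls,
        coords = coords)
  })
  names(out) <- names(mk)
  out
}

# rescaled index scores of the original image at 0-based sample coordinates
sampleScores <- function(sample, original, indexName, variant = "prose") {
  ridx <- rescaleIndex(colorIndex(original, indexName, variant))
  co <- sample@coords
  if (nrow(co) == 0L) return(numeric())
  h <- nrow(ridx@values)
  if (max(co[, 1]) >= h || max(co[, 2]) >= ncol(ridx@values))
    stop("sample coordinates fall outside the image")
  ridx@values[co[, 1] + 1L + h * co[, 2]]
}

#' Elimination-rate curves over thresholds 0..256
#'
#' For each class and every integer threshold t in 0..256, the fraction of
#' that class's sampled pixels whose rescaled index score falls below t
#' (i.e. would be eliminated by the filter at threshold t). Curves are
#' tabulated at all 257 thresholds so that both the all-kept (t = 0) and
#' all-eliminated (t = 256) endpoints appear. Classes without samples are
#' omitted.
#'
#' @param samples list of [PixelClassSample-class] (as from
#'   [extractSamples()]).
#' @param original the unmarked [RgbImage-class] the samples refer to.
#' @param indexName "exg", "exr" or "tassel".
#' @param variant tassel-index variant.
#' @return an [EliminationCurve-class].
#' @export
eliminationCurve <- function(samples, original, indexName,
                             variant = "prose") {
  indexRange(indexName, variant)  # validates the name
  if (is(samples, "PixelClassSample")) samples <- list(samples)
  thresholds <- 0:256
  perClass <- list()
  sizes <- integer()
  for (s in samples) {
    sc <- sampleScores(s, original, indexName, variant)
    if (length(sc) == 0L) next
    perClass[[s@classLabel]] <-
      vapply(thresholds, function(t) mean(sc < t), numeric(1))
    sizes[[s@classLabel]] <- length(sc)
  }
  new("EliminationCurve", indexName = indexName, variant = variant,
      perClass = perClass, sampleSizes = sizes)
}

#' Per-class elimination fractions at one threshold
#'
#' The single-threshold summary used to justify a filter threshold (for
#' instance the published over-99% soil / over-97% shadow / 0.5% foliage /
#' 13.5% tassel elimination at ExG threshold 131 on the original dataset).
#'
#' @param curve an [EliminationCurve-class].
#' @param threshold integer in 0..256.
#' @return named numeric vector of per-class fractions.
#' @export
eliminationAt <- function(curve, threshold) {
  stopifnot(is(curve, "EliminationCurve"))
  if (threshold < 0 || threshold > 256 || threshold != round(threshold))
    stop("threshold must be an integer in [0, 256]")
  vapply(curve@perClass, function(v) v[threshold + 1L], numeric(1))
}

#' Serialize an elimination curve to JSON
#'
#' @param curve an [EliminationCurve-class].
#' @param path destination JSON path.
#' @return the path, invisibly.
#' @export
writeEliminationCurve <- function(curve, path) {
  jsonlite::write_json(
    list(index_name = curve@indexName, variant = curve@variant,
         thresholds = 0:256, per_class = curve@perClass,
         sample_sizes = as.list(curve@sampleSizes)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
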