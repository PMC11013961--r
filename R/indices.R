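#' Normalize 8-bit channels to \[0, 1\]
#'
#' Divides each channel by 255, the maximum value of the 8-bit RGB range,
#' yielding the R*, G*, B* channels all color indices operate on.
#'
#' @param img an [RgbImage-class].
#' @return a [NormalizedChannels-class].
#' @export
normalizeChannels <- function(img) {
  stopifnot(is(img, "RgbImage"))
  p <- img@pixels
  ch <- function(k) matrix(p[, , k], dim(p)[1], dim(p)[2])
  new("NormalizedChannels",
      rStar = ch(1) / 255, gStar = ch(2) / 255, bStar = ch(3) / 255)
}

# registered theoretical ranges used for image-independent rescaling
indexRange <- function(indexName, variant = "prose") {
  switch(indexName,
         exg = c(-2, 2),
         exr = c(-1, 1.4),
         tassel = if (variant == "prose") c(-1, 16) else c(-1, 9),
         stop("unknown index name: ", indexName))
}

#' Excess Green Index (ExG)
#'
#' Per-pixel 2 G* - R* - B*: high for green vegetation, used to eliminate
#' soil and shadow. Theoretical range \[-2, 2\].
#'
#' @param nc a [NormalizedChannels-class] (or an [RgbImage-class], which is
#'   normalized first).
#' @return an [IndexMap-class] with indexName "exg".
#' @export
excessGreen <- function(nc) {
  nc <- asChannels(nc)
  new("IndexMap", values = 2 * nc@gStar - nc@rStar - nc@bStar,
      indexName = "exg", variant = "prose",
      rangeMin = -2, rangeMax = 2)
}

#' Excess Red Index (ExR)
#'
#' Per-pixel 1.4 R* - G*: sensitive to reddish/yellowish pixels.
#' Theoretical range \[-1, 1.4\].
#'
#' @inheritParams excessGreen
#' @return an [IndexMap-class] with indexName "exr".
#' @export
excessRed <- function(nc) {
  nc <- asChannels(nc)
  new("IndexMap", values = 1.4 * nc@rStar - nc@gStar,
      indexName = "exr", variant = "prose",
      rangeMin = -1, rangeMax = 1.4)
}

#' Tassel index
#'
#' Scores yellowish pixels (high red and green, low blue) highly, separating
#' tassels from foliage. The default ("prose") form combines the red and
#' green values, doubles the result, squares it, and subtracts blue:
#' (2 (G* + R*))^2 - B*, range \[-1, 16\]. The alternative "compact" parse
#' (2 G* + R*)^2 - B*, range \[-1, 9\], is available for comparison.
#'
#' @inheritParams excessGreen
#' @param variant "prose" (default) or "compact".
#' @return an [IndexMap-class] with indexName "tassel".
#' @export
tasselIndex <- function(nc, variant = c("prose", "compact")) {
  variant <- match.arg(variant)
  nc <- asChannels(nc)
  v <- if (variant == "prose") (2 * (nc@gStar + nc@rStar))^2 - nc@bStar
       else (2 * nc@gStar + nc@rStar)^2 - nc@bStar
  rng <- indexRange("tassel", variant)
  new("IndexMap", values = v, indexName = "tassel", variant = variant,
      rangeMin = rng[1], rangeMax = rng[2])
}

#' Compute a named color index
#'
#' @inheritParams excessGreen
#' @param indexName "exg", "exr" or "tassel".
#' @param variant tassel-index variant (ignored otherwise).
#' @return an [IndexMap-class].
#' @export
colorIndex <- function(nc, indexName, variant = "prose") {
  switch(indexName,
         exg = excessGreen(nc),
         exr = excessRed(nc),
         tassel = tasselIndex(nc, variant),
         stop("unknown index name: ", indexName))
}

asChannels <- function(x) {
  if (is(x, "RgbImage")) normalizeChannels(x)
  else if (is(x, "NormalizedChannels")) x
  else stop("expected an RgbImage or NormalizedChannels")
}

#' Rescale an index map onto \[0, 255\]
#'
#' Maps the index's fixed theoretical range linearly onto \[0, 255\] so that
#' one threshold is comparable across images; values stay floating-point.
#' The range endpoints map to 0 and 255 exactly.
#'
#' @param idx an [IndexMap-class].
#' @return a [RescaledIndexMap-class].
#' @export
rescaleIndex <- function(idx) {
  if (is(idx, "RescaledIndexMap")) return(idx)
  stopifnot(is(idx, "IndexMap"))
  v <- (idx@values - idx@rangeMin) / (idx@rangeMax - idx@rangeMin) * 255
  new("RescaledIndexMap", values = v, indexName = idx@indexName,
      variant = idx@variant, rangeMin = idx@rangeMin, rangeMax = idx@rangeMax)
}

#' Threshold a rescaled index map
#'
#' A pixel survives when its rescaled score is greater than or equal to the
#' threshold; a score below the threshold is eliminated.
#'
#' @param ridx a [RescaledIndexMap-class].
#' @param threshold real threshold in \[0, 256\]; 0 keeps every pixel, 256
#'   eliminates every pixel.
#' @return a [BinaryMask-class].
#' @export
thresholdMask <- function(ridx, threshold) {
  stopifnot(is(ridx, "RescaledIndexMap"))
  if (threshold < 0 || threshold > 256)
    stop("threshold must lie in [0, 256]")
  new("BinaryMask", keep = ridx@values >= threshold)
}

#' Two-step tassel filter
#'
#' Step 1 thresholds the rescaled Excess Green Index (removing soil and
#' shadow); step 2 thresholds the rescaled tassel index (removing foliage).
#' Step-2 scores are computed from the original pixel values, so the two
#' masks are independent and their intersection defines the surviving
#' pixels; everything else is blacked out.
#'
#' @param img an [RgbImage-class].
#' @param exgThreshold step-1 threshold on the rescaled ExG (default 131).
#' @param tasselThreshold step-2 threshold on the rescaled tassel index.
#' @param variant tassel-index variant, see [tasselIndex()].
#' @return a [FilterResult-class].
#' @export
twoStepFilter <- function(img, exgThreshold = 131, tasselThreshold,
                          variant = "prose") {
  stopifnot(is(img, "RgbImage"))
  nc <- normalizeChannels(img)
  m1 <- thresholdMask(rescaleIndex(excessGreen(nc)), exgThreshold)
  m2 <- thresholdMask(rescaleIndex(tasselIndex(nc, variant)), tasselThreshold)
  keep <- m1@keep & m2@keep
  px <- img@pixels
  px[, , 1][!keep] <- 0L
  px[, , 2][!keep] <- 0L
  px[, , 3][!keep] <- 0L
  new("FilterResult",
      filtered = rgbImage(px, img@imageId),
      step1Mask = m1, step2Mask = m2,
      thresholds = c(exg = exgThreshold, tassel = tasselThreshold))
}

#' Black out pixels outside a mask
#'
#' @param img an [RgbImage-class].
#' @param mask a [BinaryMask-class] of the same shape.
#' @return an [RgbImage-class] with non-surviving pixels set to (0, 0, 0).
#' @export
applyMask <- function(img, mask) {
  stopifnot(is(img, "RgbImage"), is(mask, "BinaryMask"))
  if (!identical(dim(img@pixels)[1:2], dim(mask@keep)))
    stop("image and mask shapes differ")
  px <- img@pixels
  px[, , 1][!mask@keep] <- 0L
  px[, , 2][!mask@keep] <- 0L
  px[, , 3][!mask@keep] <- 0L
  rgbImage(px, img@imageId)
}
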