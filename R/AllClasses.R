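#' @import methods
NULL

#' RgbImage: an 8-bit three-channel raster
#'
#' The unit of all processing in this package: a height x width x 3 array of
#' integer values in \[0, 255\] plus an image identifier. Pixel addressing is
#' (row, col), 0-based, with row 0 at the top; annotation files use the same
#' convention.
#'
#' @slot pixels integer array of dimension c(H, W, 3), values in \[0, 255\].
#' @slot imageId single character identifier.
#' @exportClass RgbImage
setClass("RgbImage",
  representation(pixels = "array", imageId = "character"),
  validity = function(object) {
    d <- dim(object@pixels)
    if (length(d) != 3L || d[3] != 3L)
      return("pixels must be an H x W x 3 array")
    if (d[1] < 1L || d[2] < 1L)
      return("image must have H >= 1 and W >= 1")
    v <- object@pixels
    if (anyNA(v) || min(v) < 0 || max(v) > 255)
      return("pixel values must lie in [0, 255]")
    if (any(v != round(v)))
      return("pixel values must be integers")
    if (length(object@imageId) != 1L || is.na(object@imageId))
      return("imageId must be a single non-NA string")
    TRUE
  })

#' NormalizedChannels: per-channel values divided by 255
#'
#' @slot rStar,gStar,bStar H x W numeric matrices in \[0, 1\].
#' @exportClass NormalizedChannels
setClass("NormalizedChannels",
  representation(rStar = "matrix", gStar = "matrix", bStar = "matrix"),
  validity = function(object) {
    d <- dim(object@rStar)
    if (!identical(d, dim(object@gStar)) || !identical(d, dim(object@bStar)))
      return("channel matrices must share dimensions")
    for (m in list(object@rStar, object@gStar, object@bStar))
      if (min(m) < 0 || max(m) > 1) return("normalized values must lie in [0, 1]")
    TRUE
  })

#' IndexMap: per-pixel raw color-index scores
#'
#' Raw scores of one of the registered color indices, together with the
#' index's fixed theoretical range used for rescaling (ExG \[-2, 2\];
#' ExR \[-1, 1.4\]; tassel index \[-1, 16\], or \[-1, 9\] for the compact
#' variant).
#'
#' @slot values H x W numeric matrix of raw scores.
#' @slot indexName one of "exg", "exr", "tassel".
#' @slot variant index formula variant ("prose" or "compact"; only meaningful
#'   for the tassel index).
#' @slot rangeMin,rangeMax the index's theoretical range.
#' @exportClass IndexMap
setClass("IndexMap",
  representation(values = "matrix", indexName = "character",
                 variant = "character", rangeMin = "numeric",
                 rangeMax = "numeric"),
  validity = function(object) {
    if (!object@indexName %in% c("exg", "exr", "tassel"))
      return("indexName must be one of exg, exr, tassel")
    if (object@rangeMin >= object@rangeMax)
      return("rangeMin must be below rangeMax")
    v <- object@values
    if (min(v) < object@rangeMin - 1e-9 || max(v) > object@rangeMax + 1e-9)
      return("raw values exceed the index's theoretical range")
    TRUE
  })

#' RescaledIndexMap: index scores linearly mapped onto \[0, 255\]
#'
#' The theoretical range of the source index maps linearly onto \[0, 255\];
#' values stay floating-point (no integer quantization). Kept as its own
#' class (same slots as [IndexMap-class]) so raw and rescaled maps cannot
#' be confused.
#'
#' @slot values H x W numeric matrix in \[0, 255\].
#' @slot indexName,variant,rangeMin,rangeMax as in [IndexMap-class].
#' @exportClass RescaledIndexMap
setClass("RescaledIndexMap",
  representation(values = "matrix", indexName = "character",
                 variant = "character", rangeMin = "numeric",
                 rangeMax = "numeric"),
  validity = function(object) {
    if (!object@indexName %in% c("exg", "exr", "tassel"))
      return("indexName must be one of exg, exr, tassel")
    v <- object@values
    if (min(v) < -1e-9 || max(v) > 255 + 1e-9)
      return("rescaled values must lie in [0, 255]")
    TRUE
  })

#' BinaryMask: pixel survival flags
#'
#' @slot keep H x W logical matrix; TRUE marks a surviving pixel.
#' @exportClass BinaryMask
setClass("BinaryMask", representation(keep = "matrix"),
  validity = function(object) {
    if (!is.logical(object@keep)) return("keep must be a logical matrix")
    if (anyNA(object@keep)) return("keep must not contain NA")
    TRUE
  })

#' FilterResult: output of the two-step color filter
#'
#' @slot filtered the input image with eliminated pixels blacked out.
#' @slot step1Mask survival mask of the Excess Green step.
#' @slot step2Mask survival mask of the tassel-index step (computed on the
#'   original pixel values).
#' @slot thresholds named numeric: c(exg = ..., tassel = ...).
#' @exportClass FilterResult
setClass("FilterResult",
  representation(filtered = "RgbImage", step1Mask = "BinaryMask",
                 step2Mask = "BinaryMask", thresholds = "numeric"))

#' PointAnnotation: tassel center locations for one image
#'
#' @slot imageId single character identifier.
#' @slot points n x 2 numeric matrix of (row, col), 0-based.
#' @exportClass PointAnnotation
setClass("PointAnnotation",
  representation(imageId = "character", points = "matrix"),
  validity = function(object) {
    p <- object@points
    if (ncol(p) != 2L) return("points must have two columns (row, col)")
    if (nrow(p) > 0 && (anyNA(p) || min(p) < 0))
      return("point coordinates must be non-negative and non-NA")
    TRUE
  })

#' BoxAnnotation: tassel bounding boxes for one image
#'
#' Boxes are (rowMin, colMin, height, width), 0-based, half-open extent.
#'
#' @slot imageId single character identifier.
#' @slot boxes n x 4 numeric matrix.
#' @exportClass BoxAnnotation
setClass("BoxAnnotation",
  representation(imageId = "character", boxes = "matrix"),
  validity = function(object) {
    b <- object@boxes
    if (ncol(b) != 4L)
      return("boxes must have four columns (rowMin, colMin, height, width)")
    if (nrow(b) > 0) {
      if (anyNA(b) || min(b[, 1:2]) < 0)
        return("box origins must be non-negative and non-NA")
      if (min(b[, 3:4]) < 1)
        return("box height and width must be >= 1")
    }
    TRUE
  })

#' PixelClassSample: labeled sample pixels of one class
#'
#' @slot imageId single character identifier.
#' @slot classLabel one of "soil", "shadow", "foliage", "tassel".
#' @slot coords n x 2 integer matrix of (row, col), 0-based.
#' @exportClass PixelClassSample
setClass("PixelClassSample",
  representation(imageId = "character", classLabel = "character",
                 coords = "matrix"),
  validity = function(object) {
    if (!object@classLabel %in% c("soil", "shadow", "foliage", "tassel"))
      return("classLabel must be one of soil, shadow, foliage, tassel")
    if (ncol(object@coords) != 2L)
      return("coords must have two columns (row, col)")
    TRUE
  })

#' EliminationCurve: per-class elimination fractions over thresholds 0..256
#'
#' For each pixel class, entry t+1 holds the fraction of sampled pixels whose
#' rescaled index score falls below threshold t, tabulated at all 257 integer
#' thresholds 0..256 so both the all-kept and all-eliminated endpoints are
#' represented. Classes without samples are absent.
#'
#' @slot indexName the index the curve was computed for.
#' @slot variant index formula variant.
#' @slot perClass named list of numeric vectors of length 257.
#' @slot sampleSizes named integer vector of per-class sample counts.
#' @exportClass EliminationCurve
setClass("EliminationCurve",
  representation(indexName = "character", variant = "character",
                 perClass = "list", sampleSizes = "integer"),
  validity = function(object) {
    for (nm in names(object@perClass)) {
      v <- object@perClass[[nm]]
      if (length(v) != 257L) return("each curve must have 257 entries")
      if (min(v) < 0 || max(v) > 1) return("fractions must lie in [0, 1]")
      if (any(diff(v) < 0)) return("curves must be non-decreasing")
    }
    TRUE
  })

#' DensityMap: Gaussian-smoothed tassel density raster
#'
#' Each annotated point contributes a unit-mass bivariate Gaussian kernel
#' evaluated on the pixel grid, truncated at 4 bandwidths and at the image
#' boundary, then renormalized; the total mass therefore equals the number
#' of source points.
#'
#' @slot values H x W non-negative numeric matrix.
#' @slot bandwidth Gaussian sigma in pixels.
#' @slot sourcePoints number of annotated points.
#' @exportClass DensityMap
setClass("DensityMap",
  representation(values = "matrix", bandwidth = "numeric",
                 sourcePoints = "integer"),
  validity = function(object) {
    if (object@bandwidth <= 0) return("bandwidth must be positive")
    if (nrow(object@values) > 0 && min(object@values) < 0)
      return("density values must be non-negative")
    if (abs(sum(object@values) - object@sourcePoints) > 1e-6)
      return("density mass must equal the number of source points")
    TRUE
  })

#' TrainingPatchSet: sub-image tensors and their local count targets
#'
#' Overlapping patchSize x patchSize sub-images flattened to rows (pixel
#' values scaled to \[0, 1\]) with the density-map sum over each footprint as
#' regression target.
#'
#' @slot patches N x (patchSize^2 * 3) numeric matrix.
#' @slot targets numeric vector of length N, non-negative.
#' @slot patchSize side length of the square patches.
#' @exportClass TrainingPatchSet
setClass("TrainingPatchSet",
  representation(patches = "matrix", targets = "numeric",
                 patchSize = "integer"),
  validity = function(object) {
    if (nrow(object@patches) != length(object@targets))
      return("one target per patch required")
    if (ncol(object@patches) != 3L * object@patchSize^2)
      return("patch width must equal 3 * patchSize^2")
    if (length(object@targets) > 0 && min(object@targets) < -1e-9)
      return("targets must be non-negative")
    TRUE
  })

#' CounterConfig: hyperparameters of the counting-by-regression engine
#'
#' Defaults follow the published protocol: 32 x 32 sub-images with stride 8,
#' Gaussian bandwidth 8 px, learning rate 1e-4, at most 50 epochs with early
#' stopping patience 5.
#'
#' @slot patchSize sub-image side length (default 32).
#' @slot stride sub-image stride in pixels (default 8).
#' @slot bandwidth Gaussian sigma in pixels for density maps (default 8).
#' @slot learningRate Adam learning rate (default 1e-4).
#' @slot maxEpochs maximum training epochs (default 50).
#' @slot patience epochs without validation improvement before stopping.
#' @slot batchSize minibatch size (default 256).
#' @slot validationFraction fraction of patches held out (default 0.1).
#' @slot convWidths channel widths of the four conv blocks.
#' @slot dropout dropout probability after each block (default 0.25).
#' @slot seed master seed for split, init, shuffling, dropout.
#' @exportClass CounterConfig
setClass("CounterConfig",
  representation(patchSize = "integer", stride = "integer",
                 bandwidth = "numeric", learningRate = "numeric",
                 maxEpochs = "integer", patience = "integer",
                 batchSize = "integer", validationFraction = "numeric",
                 convWidths = "integer", dropout = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (object@stride < 1L || object@patchSize < object@stride)
      return("need patchSize >= stride >= 1")
    if (object@bandwidth <= 0) return("bandwidth must be positive")
    if (object@validationFraction <= 0 || object@validationFraction >= 1)
      return("validationFraction must lie strictly between 0 and 1")
    npool <- length(object@convWidths) - 1L
    if (object@patchSize %% (2L^npool) != 0L)
      return("patchSize must be divisible by 2^(number of pooling steps)")
    if (object@dropout < 0 || object@dropout >= 1)
      return("dropout must lie in [0, 1)")
    TRUE
  })

#' CounterModel: a trained convolutional count regressor
#'
#' @slot config the CounterConfig used for training.
#' @slot params learned parameters (conv blocks with batch-normalization
#'   statistics plus the scalar regression head).
#' @slot trainLog data.frame with per-epoch training and validation L1 loss.
#' @slot bestEpoch epoch whose parameters are stored.
#' @exportClass CounterModel
setClass("CounterModel",
  representation(config = "CounterConfig", params = "list",
                 trainLog = "data.frame", bestEpoch = "integer"))

#' SceneConfig: parameters of the synthetic plot-scene generator
#'
#' @slot height,width scene size in pixels (default 128 x 256, a scaled-down
#'   plot crop).
#' @slot nTassels fixed tassel count, or NA to draw uniformly from
#'   tasselRange.
#' @slot tasselRange inclusive range for random tassel counts (default 5..25).
#' @slot palette per-class color means and jitters (see [defaultPalette()]).
#' @slot tasselShape list(nBranches, branchLength, thickness) of the branched
#'   tassel glyph.
#' @slot shadowFraction approximate fraction of the scene covered by shadow.
#' @slot nCanopies number of elliptical foliage canopies.
#' @slot seed scene seed.
#' @exportClass SceneConfig
setClass("SceneConfig",
  representation(height = "integer", width = "integer", nTassels = "integer",
                 tasselRange = "integer", palette = "list",
                 tasselShape = "list", shadowFraction = "numeric",
                 nCanopies = "integer", seed = "integer"),
  validity = function(object) {
    if (object@height < 48L || object@width < 48L)
      return("scene must be at least 48 x 48")
    if (!is.na(object@nTassels) && object@nTassels < 0L)
      return("nTassels must be >= 0")
    if (object@shadowFraction < 0 || object@shadowFraction > 0.5)
      return("shadowFraction must lie in [0, 0.5]")
    TRUE
  })

#' SyntheticScene: one generated plot scene with full ground truth
#'
#' @slot image the rendered RGB scene.
#' @slot points tassel center annotations.
#' @slot boxes tassel bounding boxes.
#' @slot classMap H x W character matrix with labels soil/shadow/foliage/
#'   tassel.
#' @slot markerImage copy of the image with a random subsample of each class
#'   marked in the pure marker colors (soil blue, shadow green, foliage red,
#'   tassel yellow).
#' @slot config the SceneConfig that produced the scene.
#' @exportClass SyntheticScene
setClass("SyntheticScene",
  representation(image = "RgbImage", points = "PointAnnotation",
                 boxes = "BoxAnnotation", classMap = "matrix",
                 markerImage = "RgbImage", config = "SceneConfig"))

#' SweepResult: r-squared versus step-2 filter threshold
#'
#' @slot thresholds integer thresholds 0..255.
#' @slot rSquared r-squared of predicted versus observed counts per threshold;
#'   degenerate thresholds (constant predictions) record 0.
#' @slot degenerate logical flags marking degenerate thresholds.
#' @slot bestThreshold argmax threshold (ties resolve to the lowest).
#' @slot bestRSquared the maximum r-squared.
#' @exportClass SweepResult
setClass("SweepResult",
  representation(thresholds = "integer", rSquared = "numeric",
                 degenerate = "logical", bestThreshold = "integer",
                 bestRSquared = "numeric"),
  validity = function(object) {
    n <- length(object@thresholds)
    if (length(object@rSquared) != n || length(object@degenerate) != n)
      return("thresholds, rSquared and degenerate must align")
    TRUE
  })
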