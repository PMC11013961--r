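#' Build a Gaussian density map from point annotations
#'
#' Each annotated point contributes a bivariate Gaussian kernel of standard
#' deviation `bandwidth` (pixels), evaluated on the integer pixel grid,
#' truncated at 4 bandwidths and at the image boundary, and renormalized to
#' unit mass, so the total mass of the map equals the number of points
#' exactly (kernels of boundary points are renormalized rather than losing
#' mass off the edge).
#'
#' @param pts a [PointAnnotation-class]; all points must lie inside `shape`.
#' @param shape integer c(H, W).
#' @param bandwidth Gaussian sigma in pixels (> 0).
#' @return a [DensityMap-class].
#' @export
buildDensityMap <- function(pts, shape, bandwidth) {
  stopifnot(is(pts, "PointAnnotation"), bandwidth > 0)
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  assertPointsInside(pts, c(H, W))
  dm <- matrix(0, H, W)
  p <- pts@points
  r4 <- 4 * bandwidth
  for (k in seq_len(nrow(p))) {
    r0 <- p[k, 1]; c0 <- p[k, 2]
    ri <- max(0, ceiling(r0 - r4)):min(H - 1, floor(r0 + r4))
    ci <- max(0, ceiling(c0 - r4)):min(W - 1, floor(c0 + r4))
    kr <- exp(-(ri - r0)^2 / (2 * bandwidth^2))
    kc <- exp(-(ci - c0)^2 / (2 * bandwidth^2))
    kern <- outer(kr, kc)
    dm[ri + 1, ci + 1] <- dm[ri + 1, ci + 1] + kern / sum(kern)
  }
  new("DensityMap", values = dm, bandwidth = bandwidth,
      sourcePoints = nrow(p))
}

# top-left offsets (0-based) of all fully contained windows
windowOffsets <- function(H, W, patchSize, stride) {
  if (H < patchSize || W < patchSize)
    stop("image (", H, " x ", W, ") is smaller than the patch size ",
         patchSize, "; no padding is applied")
  list(rows = seq(0L, H - patchSize, by = stride),
       cols = seq(0L, W - patchSize, by = stride))
}

# flatten all windows of an image into an N x (ps^2*3) matrix, values in [0,1]
patchMatrix <- function(img, patchSize, stride) {
  p <- img@pixels / 255
  d <- dim(p)
  off <- windowOffsets(d[1], d[2], patchSize, stride)
  n <- length(off$rows) * length(off$cols)
  out <- matrix(0, n, patchSize^2 * 3)
  k <- 1L
  for (a in off$rows) {
    for (b in off$cols) {
      out[k, ] <- as.vector(p[(a + 1):(a + patchSize),
                              (b + 1):(b + patchSize), ])
      k <- k + 1L
    }
  }
  out
}

# summed-area table lookup of density sums over all window footprints
windowTargets <- function(dm, patchSize, stride) {
  v <- dm@values
  H <- nrow(v); W <- ncol(v)
  off <- windowOffsets(H, W, patchSize, stride)
  sat <- rbind(0, cbind(0, apply(apply(v, 2, cumsum), 1, cumsum)))
  # sat is (W+1) x (H+1) after the transpose from the second apply
  tgt <- numeric(length(off$rows) * length(off$cols))
  k <- 1L
  for (a in off$rows) {
    for (b in off$cols) {
      tgt[k] <- sat[b + patchSize + 1, a + patchSize + 1] -
        sat[b + 1, a + patchSize + 1] - sat[b + patchSize + 1, a + 1] +
        sat[b + 1, a + 1]
      k <- k + 1L
    }
  }
  tgt
}

#' Decompose an image into overlapping training patches
#'
#' Windows of `patchSize` x `patchSize` are placed at all top-left offsets
#' (a stride, b stride) that keep the window fully inside the image (no
#' padding), giving (floor((H - ps) / stride) + 1) *
#' (floor((W - ps) / stride) + 1) patches. Each patch's regression target is
#' the density-map sum over its footprint (the local expected count).
#'
#' @param img an [RgbImage-class].
#' @param dm the matching [DensityMap-class] (same shape).
#' @param cfg a [CounterConfig-class] supplying patchSize and stride.
#' @return a [TrainingPatchSet-class].
#' @export
extractPatches <- function(img, dm, cfg = counterConfig()) {
  stopifnot(is(img, "RgbImage"), is(dm, "DensityMap"))
  if (!identical(dim(img@pixels)[1:2], dim(dm@values)))
    stop("image and density map shapes differ")
  X <- patchMatrix(img, cfg@patchSize, cfg@stride)
  tgt <- pmax(0, windowTargets(dm, cfg@patchSize, cfg@stride))
  new("TrainingPatchSet", patches = X, targets = tgt,
      patchSize = cfg@patchSize)
}

#' Combine training patch sets
#'
#' @param ... [TrainingPatchSet-class] objects with equal patch size.
#' @return a single [TrainingPatchSet-class].
#' @export
combinePatchSets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) &&
      !is(sets[[1]], "TrainingPatchSet")) sets <- sets[[1]]
  ps <- unique(vapply(sets, function(s) s@patchSize, integer(1)))
  if (length(ps) != 1L) stop("patch sizes differ")
  new("TrainingPatchSet",
      patches = do.call(rbind, lapply(sets, function(s) s@patches)),
      targets = do.call(c, lapply(sets, function(s) s@targets)),
      patchSize = ps)
}
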