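#' Construct an RgbImage
#'
#' @param pixels H x W x 3 array of integer values in \[0, 255\].
#' @param imageId image identifier.
#' @return an [RgbImage-class] object.
#' @export
rgbImage <- function(pixels, imageId = "image") {
  storage.mode(pixels) <- "integer"
  new("RgbImage", pixels = pixels, imageId = as.character(imageId))
}

#' Read an RGB raster image
#'
#' PNG is the canonical (lossless) format; JPEG is accepted on read only.
#' An alpha channel, if present, is dropped; single-channel (grayscale)
#' input is rejected.
#'
#' @param path path to a PNG or JPEG file.
#' @param imageId identifier to attach; defaults to the file name without
#'   extension.
#' @return an [RgbImage-class].
#' @export
readRgbImage <- function(path, imageId = NULL) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  if (is.null(imageId)) imageId <- sub("\\.[^.]+$", "", basename(path))
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "png") {
    a <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    e <- EBImage::readImage(path)
    a <- EBImage::imageData(e)
    # EBImage stores (x, y, channel); transpose to (row, col, channel)
    if (length(dim(a)) == 3L) a <- aperm(a, c(2L, 1L, 3L))
  } else {
    stop("unsupported image format: ", ext)
  }
  if (length(dim(a)) != 3L || dim(a)[3] == 1L)
    stop("single-channel (grayscale) images are not supported: ", path)
  if (dim(a)[3] == 4L) a <- a[, , 1:3, drop = FALSE]
  if (dim(a)[3] != 3L) stop("expected 3 or 4 channels in ", path)
  rgbImage(round(a * 255), imageId)
}

#' Write an RgbImage as PNG
#'
#' @param img an [RgbImage-class].
#' @param path destination path (PNG).
#' @return the path, invisibly.
#' @export
writeRgbImage <- function(img, path) {
  stopifnot(is(img, "RgbImage"))
  png::writePNG(img@pixels / 255, path)
  invisible(path)
}

#' Write a BinaryMask as a black/white PNG
#'
#' @param mask a [BinaryMask-class].
#' @param path destination path (PNG).
#' @return the path, invisibly.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "BinaryMask"))
  png::writePNG(mask@keep * 1, path)
  invisible(path)
}

#' Read point or box annotations from CSV
#'
#' Points use the schema (image_id, row, col); boxes use
#' (image_id, row_min, col_min, height, width). Coordinates are 0-based
#' (row, col) with row 0 at the top. Records are grouped per image_id.
#'
#' @param path CSV file with a header.
#' @param kind "points" or "boxes".
#' @return a named list of [PointAnnotation-class] or [BoxAnnotation-class]
#'   objects, one per image_id, in first-appearance order.
#' @export
readAnnotations <- function(path, kind = c("points", "boxes")) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- if (kind == "points") c("image_id", "row", "col")
          else c("image_id", "row_min", "col_min", "height", "width")
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("annotation file lacks column(s): ", paste(missing, collapse = ", "))
  if (kind == "boxes" && nrow(df) > 0 && min(df$height, df$width) < 1)
    stop("box height and width must be >= 1")
  ids <- unique(df$image_id)
  out <- lapply(ids, function(id) {
    rows <- df[df$image_id == id, , drop = FALSE]
    if (kind == "points") {
      new("PointAnnotation", imageId = id,
          points = cbind(row = rows$row, col = rows$col))
    } else {
      new("BoxAnnotation", imageId = id,
          boxes = cbind(rowMin = rows$row_min, colMin = rows$col_min,
                        height = rows$height, width = rows$width))
    }
  })
  names(out) <- ids
  out
}

#' Write annotations to CSV
#'
#' @param anns a single annotation object or a list of them (all the same
#'   kind).
#' @param path destination CSV path.
#' @return the path, invisibly.
#' @export
writeAnnotations <- function(anns, path) {
  if (is(anns, "PointAnnotation") || is(anns, "BoxAnnotation"))
    anns <- list(anns)
  stopifnot(length(anns) > 0)
  if (is(anns[[1]], "PointAnnotation")) {
    rows <- lapply(anns, function(a)
      if (nrow(a@points)) data.frame(image_id = a@imageId,
                                     row = a@points[, 1],
                                     col = a@points[, 2]) else NULL)
    df <- do.call(rbind, rows)
    if (is.null(df))
      df <- data.frame(image_id = character(), row = numeric(),
                       col = numeric())
  } else {
    rows <- lapply(anns, function(a)
      if (nrow(a@boxes)) data.frame(image_id = a@imageId,
                                    row_min = a@boxes[, 1],
                                    col_min = a@boxes[, 2],
                                    height = a@boxes[, 3],
                                    width = a@boxes[, 4]) else NULL)
    df <- do.call(rbind, rows)
    if (is.null(df))
      df <- data.frame(image_id = character(), row_min = numeric(),
                       col_min = numeric(), height = numeric(),
                       width = numeric())
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Convert box annotations to center points
#'
#' Each box (rowMin, colMin, height, width) yields one point at
#' (rowMin + height / 2, colMin + width / 2), bridging bounding-box labels
#' to the point-referenced input the density-map engine expects.
#'
#' @param a a [BoxAnnotation-class].
#' @return a [PointAnnotation-class] with one point per box.
#' @export
boxesToPoints <- function(a) {
  stopifnot(is(a, "BoxAnnotation"))
  b <- a@boxes
  pts <- cbind(row = b[, 1] + b[, 3] / 2, col = b[, 2] + b[, 4] / 2)
  if (nrow(b) == 0L) pts <- cbind(row = numeric(), col = numeric())
  new("PointAnnotation", imageId = a@imageId, points = pts)
}

# check that all points of `pts` fall inside an H x W image
assertPointsInside <- function(pts, shape) {
  p <- pts@points
  if (nrow(p) == 0L) return(invisible(TRUE))
  if (max(p[, 1]) > shape[1] - 1 || max(p[, 2]) > shape[2] - 1 ||
      min(p) < 0)
    stop("annotation points fall outside the image bounds")
  invisible(TRUE)
}
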