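#' Default synthetic-scene palette
#'
#' Class color means and jitters chosen so that the color relationships the
#' two filters assume hold by construction: soil (120,90,60) sits exactly at
#' rescaled ExG 127.5 (eliminated at threshold 131), shadow is dark and
#' ExG-negative, foliage (50,140,40) passes the ExG step but scores low
#' (about 46) on the rescaled tassel index, and tassel (200,180,80) passes
#' both steps (rescaled ExG about 147.5, rescaled tassel index about 143.5).
#' Foliage carries an additional per-canopy brightness offset so that
#' elimination proceeds canopy by canopy, as in real scenes where whole
#' plants differ in illumination.
#'
#' The jitters are sized so the contract is strict: with soil/shadow jitter
#' 3, no soil or shadow pixel can reach rescaled ExG 131; with foliage
#' offsets up to 6 plus pixel jitter 2, no foliage pixel can exceed a
#' rescaled tassel score of about 53; with tassel jitter 10, no tassel pixel
#' can fall below about 129. The documented optimal step-2 threshold for
#' this palette is 90 (attribute `optimalThreshold`), the midpoint region
#' of that separation gap.
#'
#' @return named list of per-class settings with attribute
#'   `optimalThreshold`.
#' @export
defaultPalette <- function() {
  p <- list(
    soil = list(mean = c(120, 90, 60), jitter = 3),
    shadow = list(mean = c(40, 40, 45), jitter = 3),
    foliage = list(mean = c(50, 140, 40), jitter = 2, canopyJitter = 6),
    tassel = list(mean = c(200, 180, 80), jitter = 10))
  attr(p, "optimalThreshold") <- 90
  p
}

#' Synthetic-scene configuration
#'
#' @param height,width scene size (default 128 x 256, a scaled-down plot
#'   crop).
#' @param nTassels fixed tassel count, or NA to draw uniformly from
#'   `tasselRange`.
#' @param tasselRange inclusive range of random tassel counts.
#' @param palette see [defaultPalette()].
#' @param tasselShape list(nBranches, branchLength, thickness) of the
#'   branched glyph.
#' @param shadowFraction approximate shadow coverage.
#' @param nCanopies number of elliptical foliage canopies.
#' @param seed scene seed.
#' @return a [SceneConfig-class].
#' @export
sceneConfig <- function(height = 128L, width = 256L, nTassels = NA_integer_,
                        tasselRange = c(5L, 25L),
                        palette = defaultPalette(),
                        tasselShape = list(nBranches = 5L,
                                           branchLength = 7L,
                                           thickness = 2L),
                        shadowFraction = 0.12, nCanopies = 6L, seed = 1L) {
  new("SceneConfig", height = as.integer(height), width = as.integer(width),
      nTassels = as.integer(nTassels),
      tasselRange = as.integer(tasselRange), palette = palette,
      tasselShape = tasselShape, shadowFraction = shadowFraction,
      nCanopies = as.integer(nCanopies), seed = as.integer(seed))
}

jitterValues <- function(j, n) {
  if (j == 0) rep(0L, n) else sample(seq.int(-j, j), n, replace = TRUE)
}

# paint `mask` pixels with mean + offset + per-pixel jitter
paintClass <- function(px, mask, mean, jitter, offset = 0) {
  n <- sum(mask)
  for (ch in 1:3) {
    m <- px[, , ch]
    m[mask] <- clamp255(mean[ch] + offset + jitterValues(jitter, n))
    px[, , ch] <- m
  }
  px
}

ellipseMask <- function(H, W, r0, c0, a, b) {
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  ((rows - r0) / a)^2 + ((cols - c0) / b)^2 <= 1
}

# pixel coordinates (1-based) of a branched tassel glyph centered at (r0, c0)
tasselGlyph <- function(r0, c0, shape) {
  L <- shape$branchLength
  angles <- seq(200, 340, length.out = shape$nBranches) * pi / 180
  rs <- integer(); cs <- integer()
  for (th in angles) {
    s <- 0:L
    rs <- c(rs, round(r0 + s * sin(th)))
    cs <- c(cs, round(c0 + s * cos(th)))
  }
  if (shape$thickness >= 2L) {
    rs <- c(rs, rs)
    cs <- c(cs, cs + 1L)
  }
  u <- !duplicated(cbind(rs, cs))
  cbind(row = rs[u], col = cs[u])
}

#' Generate one synthetic plot scene
#'
#' Renders a soil-textured background, elliptical foliage canopies with
#' per-canopy brightness, dark elliptical shadows, and branched yellowish
#' tassel glyphs at recorded centers (drawn last, without blur, so tassel
#' pixels keep their palette color exactly). Produces the image, point and
#' box annotations, a per-pixel class map consistent with what was drawn,
#' and a marker image with a random subsample of each class marked in the
#' pure sampling colors. Deterministic per seed. The palette's separation
#' contract is verified on the generated pixels and a violation raises a
#' configuration error naming the failing class.
#'
#' @param cfg a [SceneConfig-class].
#' @param imageId identifier for the generated image.
#' @param nMarked marker pixels sampled per class for the marker image.
#' @param checkContract verify the palette separation contract (default
#'   TRUE).
#' @return a [SyntheticScene-class].
#' @export
generateScene <- function(cfg = sceneConfig(), imageId = "scene",
                          nMarked = 200L, checkContract = TRUE) {
  stopifnot(is(cfg, "SceneConfig"))
  withSeed(cfg@seed, {
    H <- cfg@height; W <- cfg@width
    pal <- cfg@palette
    px <- array(0L, c(H, W, 3))
    classMap <- matrix("soil", H, W)
    px <- paintClass(px, matrix(TRUE, H, W), pal$soil$mean, pal$soil$jitter)

    for (i in seq_len(cfg@nCanopies)) {
      r0 <- runif(1, 0.15 * H, 0.85 * H)
      c0 <- runif(1, 0.08 * W, 0.92 * W)
      a <- runif(1, 0.12, 0.22) * H
      b <- runif(1, 0.08, 0.16) * W
      mask <- ellipseMask(H, W, r0, c0, a, b)
      offset <- jitterValues(pal$foliage$canopyJitter %||% 0, 1)
      px <- paintClass(px, mask, pal$foliage$mean, pal$foliage$jitter,
                       offset)
      classMap[mask] <- "foliage"
    }

    nShadow <- round(cfg@shadowFraction * H * W / (pi * 10 * 14))
    for (i in seq_len(nShadow)) {
      r0 <- runif(1, 1, H); c0 <- runif(1, 1, W)
      mask <- ellipseMask(H, W, r0, c0, runif(1, 6, 14), runif(1, 8, 20))
      px <- paintClass(px, mask, pal$shadow$mean, pal$shadow$jitter)
      classMap[mask] <- "shadow"
    }

    nT <- if (is.na(cfg@nTassels))
      sample(seq.int(cfg@tasselRange[1], cfg@tasselRange[2]), 1)
    else cfg@nTassels
    shape <- cfg@tasselShape
    margin <- shape$branchLength + 3L
    minDist <- 2 * (shape$branchLength + 2L)
    centers <- matrix(0L, 0, 2)
    tries <- 0L
    while (nrow(centers) < nT) {
      tries <- tries + 1L
      if (tries > 20000L)
        stop("could not place ", nT, " tassels with minimum separation ",
             minDist, " in a ", H, " x ", W, " scene")
      r0 <- sample(seq.int(margin + 1L, H - margin), 1)
      c0 <- sample(seq.int(margin + 1L, W - margin), 1)
      if (nrow(centers) == 0L ||
          min(sqrt((centers[, 1] - r0)^2 + (centers[, 2] - c0)^2)) >=
            minDist)
        centers <- rbind(centers, c(r0, c0))
    }
    boxes <- matrix(0, nT, 4)
    for (k in seq_len(nT)) {
      g <- tasselGlyph(centers[k, 1], centers[k, 2], shape)
      idx <- cbind(g[, 1], g[, 2])
      for (ch in 1:3) {
        m <- px[, , ch]
        m[idx] <- clamp255(pal$tassel$mean[ch] +
                             jitterValues(pal$tassel$jitter, nrow(g)))
        px[, , ch] <- m
      }
      classMap[idx] <- "tassel"
      boxes[k, ] <- c(min(g[, 1]) - 1, min(g[, 2]) - 1,
                      diff(range(g[, 1])) + 1, diff(range(g[, 2])) + 1)
    }
    colnames(boxes) <- c("rowMin", "colMin", "height", "width")
    pts <- centers - 1  # to 0-based
    if (nT == 0L) pts <- matrix(numeric(), 0, 2)
    colnames(pts) <- c("row", "col")

    img <- rgbImage(px, imageId)

    marker <- px
    mk <- markerColors()
    for (cls in names(mk)) {
      w <- which(classMap == cls)
      if (length(w) == 0L) next
      sel <- if (length(w) > nMarked) sample(w, nMarked) else w
      for (ch in 1:3) {
        m <- marker[, , ch]
        m[sel] <- mk[[cls]][ch]
        marker[, , ch] <- m
      }
    }

    scene <- new("SyntheticScene", image = img,
                 points = new("PointAnnotation", imageId = imageId,
                              points = pts),
                 boxes = new("BoxAnnotation", imageId = imageId,
                             boxes = boxes),
                 classMap = classMap,
                 markerImage = rgbImage(marker, paste0(imageId, "_marker")),
                 config = cfg)
    if (checkContract) checkSeparationContract(scene)
    scene
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Verify the palette separation contract on a generated scene
#'
#' Checks, on the scene's actual pixels: at least 99 percent of soil and of
#' shadow pixels fall below rescaled ExG 131; at least 95 percent of foliage
#' and of tassel pixels reach it; and at the palette's documented optimal
#' step-2 threshold, at least 95 percent of foliage pixels but at most 20
#' percent of tassel pixels are eliminated by the tassel index.
#'
#' @param scene a [SyntheticScene-class].
#' @param exgThreshold step-1 threshold checked (default 131).
#' @return invisibly TRUE; raises a configuration error naming the failing
#'   class otherwise.
#' @export
checkSeparationContract <- function(scene, exgThreshold = 131) {
  nc <- normalizeChannels(scene@image)
  exg <- rescaleIndex(excessGreen(nc))@values
  tas <- rescaleIndex(tasselIndex(nc))@values
  tOpt <- attr(scene@config@palette, "optimalThreshold") %||% 90
  fail <- function(cls, what)
    stop(errorCondition(
      sprintf("palette separation contract violated for class '%s' (%s)",
              cls, what),
      class = c("tasselcount_palette", "error", "condition")))
  for (cls in c("soil", "shadow")) {
    v <- exg[scene@classMap == cls]
    if (length(v) && mean(v < exgThreshold) < 0.99)
      fail(cls, sprintf("under %.0f%% eliminated by ExG at %g", 99,
                        exgThreshold))
  }
  for (cls in c("foliage", "tassel")) {
    v <- exg[scene@classMap == cls]
    if (length(v) && mean(v >= exgThreshold) < 0.95)
      fail(cls, sprintf("under %.0f%% surviving ExG at %g", 95,
                        exgThreshold))
  }
  vf <- tas[scene@classMap == "foliage"]
  if (length(vf) && mean(vf < tOpt) < 0.95)
    fail("foliage", sprintf("under 95%% eliminated by tassel index at %g",
                            tOpt))
  vt <- tas[scene@classMap == "tassel"]
  if (length(vt) && mean(vt < tOpt) > 0.20)
    fail("tassel", sprintf("over 20%% eliminated by tassel index at %g",
                           tOpt))
  invisible(TRUE)
}

#' Empirical step-2 separation band of generated scenes
#'
#' Pools foliage and tassel pixels over the given scenes and returns the
#' integer threshold band \[lo, hi\] where at least `foliageMin` of foliage
#' pixels are eliminated by the rescaled tassel index while at most
#' `tasselMax` of tassel pixels are — the band in which the second filter
#' step isolates tassels from foliage.
#'
#' @param scenes a [SyntheticScene-class] or list of them.
#' @param foliageMin required foliage elimination (default 0.95).
#' @param tasselMax tolerated tassel elimination (default 0.20).
#' @param variant tassel-index variant.
#' @return named integer vector c(lo, hi).
#' @export
separationBand <- function(scenes, foliageMin = 0.95, tasselMax = 0.20,
                           variant = "prose") {
  if (is(scenes, "SyntheticScene")) scenes <- list(scenes)
  fol <- numeric(); tas <- numeric()
  for (s in scenes) {
    v <- rescaleIndex(tasselIndex(normalizeChannels(s@image),
                                  variant))@values
    fol <- c(fol, v[s@classMap == "foliage"])
    tas <- c(tas, v[s@classMap == "tassel"])
  }
  stopifnot(length(fol) > 0, length(tas) > 0)
  ts <- 0:256
  folElim <- vapply(ts, function(t) mean(fol < t), numeric(1))
  tasElim <- vapply(ts, function(t) mean(tas < t), numeric(1))
  ok <- folElim >= foliageMin & tasElim <= tasselMax
  if (!any(ok))
    stop(errorCondition("no separation band exists for these scenes",
                        class = c("tasselcount_palette", "error",
                                  "condition")))
  c(lo = ts[which(ok)[1]], hi = ts[which(ok)[length(which(ok))]])
}

#' Generate a list of scenes in memory
#'
#' Per-scene seeds are derived from the master seed, so the whole list is
#' reproducible from `seed` alone.
#'
#' @param nScenes number of scenes.
#' @param config template [SceneConfig-class]; its seed slot is replaced by
#'   derived per-scene seeds.
#' @param seed master seed.
#' @return list of [SyntheticScene-class] objects named scene_001, ...
#' @export
generateScenes <- function(nScenes, config = sceneConfig(), seed = 1L) {
  seeds <- deriveSeeds(seed, nScenes)
  ids <- sprintf("scene_%03d", seq_len(nScenes))
  out <- lapply(seq_len(nScenes), function(i) {
    cfg <- config
    cfg@seed <- seeds[i]
    generateScene(cfg, imageId = ids[i])
  })
  names(out) <- ids
  out
}

classCodes <- c(soil = 1L, shadow = 2L, foliage = 3L, tassel = 4L)

#' Random train/test split of image ids
#'
#' Draws round(trainFraction * n) ids into the training split (so 323
#' images at the default 0.8 split 258 train / 65 test), the rest into the
#' test split; deterministic per seed.
#'
#' @param ids character vector of image ids.
#' @param trainFraction fraction assigned to training (default 0.8).
#' @param seed split seed.
#' @return list with `train` and `test` id vectors (both sorted).
#' @export
splitIds <- function(ids, trainFraction = 0.8, seed = 1L) {
  nTrain <- round(trainFraction * length(ids))
  train <- withSeed(seed + 1L, sort(sample(ids, nTrain)))
  list(train = train, test = setdiff(ids, train))
}

#' Generate a synthetic dataset on disk
#'
#' Writes per-scene PNG images, marker images, class maps (single-channel
#' PNG with codes soil=1, shadow=2, foliage=3, tassel=4), point and box
#' annotation CSVs, a ground-truth count CSV, a random train/test split
#' (default 80/20, so 323 scenes split 258/65), and a JSON manifest holding
#' the master seed, per-scene seeds and the split.
#'
#' @param nScenes number of scenes (>= 1).
#' @param dir output directory; must be empty or absent unless
#'   `force = TRUE`.
#' @param config template [SceneConfig-class].
#' @param seed master seed.
#' @param trainFraction fraction of scenes assigned to the training split.
#' @param force overwrite a non-empty directory.
#' @return the manifest, invisibly.
#' @export
generateDataset <- function(nScenes, dir, config = sceneConfig(),
                            seed = 1L, trainFraction = 0.8, force = FALSE) {
  stopifnot(nScenes >= 1L)
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force)
    stop("output directory ", dir, " is not empty (use force = TRUE)")
  dir.create(file.path(dir, "images"), showWarnings = FALSE,
             recursive = TRUE)
  dir.create(file.path(dir, "markers"), showWarnings = FALSE)
  dir.create(file.path(dir, "classmaps"), showWarnings = FALSE)
  scenes <- generateScenes(nScenes, config, seed)
  for (s in scenes) {
    id <- s@image@imageId
    writeRgbImage(s@image, file.path(dir, "images", paste0(id, ".png")))
    writeRgbImage(s@markerImage,
                  file.path(dir, "markers", paste0(id, ".png")))
    codes <- matrix(classCodes[s@classMap], nrow(s@classMap))
    png::writePNG(codes / 255,
                  file.path(dir, "classmaps", paste0(id, ".png")))
  }
  writeAnnotations(lapply(scenes, function(s) s@points),
                   file.path(dir, "points.csv"))
  writeAnnotations(lapply(scenes, function(s) s@boxes),
                   file.path(dir, "boxes.csv"))
  truth <- data.frame(image_id = names(scenes),
                      count = vapply(scenes,
                                     function(s) nrow(s@points@points),
                                     integer(1)))
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  split <- splitIds(names(scenes), trainFraction, seed)
  manifest <- list(seed = seed, n_scenes = nScenes,
                   scene_seeds = deriveSeeds(seed, nScenes),
                   height = config@height, width = config@width,
                   train = split$train, test = split$test)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
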