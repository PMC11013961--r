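test_that("scene generation is deterministic and bookkeeping is exact", {
  cfg <- tinyScene(60, nTassels = 12L, height = 96L, width = 128L)
  s1 <- generateScene(cfg, "d1")
  s2 <- generateScene(cfg, "d1")
  expect_identical(pixels(s1@image), pixels(s2@image))
  expect_identical(s1@classMap, s2@classMap)
  expect_identical(pixels(s1@markerImage), pixels(s2@markerImage))

  expect_equal(nrow(s1@points@points), 12L)
  expect_equal(nrow(s1@boxes@boxes), 12L)
  for (k in 1:12) {
    p <- s1@points@points[k, ]
    b <- s1@boxes@boxes[k, ]
    # point inside its box
    expect_gte(p[1], b[1]); expect_lt(p[1], b[1] + b[3])
    expect_gte(p[2], b[2]); expect_lt(p[2], b[2] + b[4])
    # annotated center lies on a tassel-class pixel
    expect_identical(s1@classMap[p[1] + 1, p[2] + 1], "tassel")
    # box center lies within the tassel glyph
    cr <- floor(b[1] + b[3] / 2); cc <- floor(b[2] + b[4] / 2)
    expect_identical(s1@classMap[cr + 1, cc + 1], "tassel")
  }
})

test_that("a zero-tassel scene has no tassel pixels or annotations", {
  s <- generateScene(tinyScene(61, nTassels = 0L), "z")
  expect_equal(nrow(s@points@points), 0L)
  expect_equal(nrow(s@boxes@boxes), 0L)
  expect_false(any(s@classMap == "tassel"))
})

test_that("marker image marks only pixels of the encoded class", {
  s <- generateScene(tinyScene(62), "m")
  mk <- markerColors()
  for (cls in names(mk)) {
    hit <- s@markerImage@pixels[, , 1] == mk[[cls]][1] &
      s@markerImage@pixels[, , 2] == mk[[cls]][2] &
      s@markerImage@pixels[, , 3] == mk[[cls]][3]
    expect_true(all(s@classMap[hit] == cls))
  }
})

test_that("palette separation contract holds and violations are diagnosed", {
  s <- generateScene(tinyScene(63), "c")
  expect_true(checkSeparationContract(s))
  nc <- normalizeChannels(s@image)
  exg <- rescaleIndex(excessGreen(nc))@values
  for (cls in c("soil", "shadow"))
    expect_gte(mean(exg[s@classMap == cls] < 131), 0.99)
  for (cls in c("foliage", "tassel"))
    expect_gte(mean(exg[s@classMap == cls] >= 131), 0.95)
  tas <- rescaleIndex(tasselIndex(nc))@values
  band <- separationBand(s)
  tOpt <- attr(defaultPalette(), "optimalThreshold")
  expect_lte(band[["lo"]], tOpt)
  expect_gte(band[["hi"]], tOpt)
  expect_gte(mean(tas[s@classMap == "foliage"] < tOpt), 0.95)
  expect_lte(mean(tas[s@classMap == "tassel"] < tOpt), 0.20)

  # a palette that colors foliage like tassels cannot separate them
  bad <- defaultPalette()
  bad$foliage$mean <- bad$tassel$mean
  expect_error(generateScene(sceneConfig(palette = bad, seed = 1)),
               class = "tasselcount_palette")
  expect_match(tryCatch(generateScene(sceneConfig(palette = bad, seed = 1)),
                        error = conditionMessage), "foliage")
})

test_that("dataset writer emits files, annotations and a seeded split", {
  dir <- withr::local_tempdir()
  man <- generateDataset(5, dir, config = tinyScene(64), seed = 9L)
  expect_length(man$train, 4)
  expect_length(man$test, 1)
  expect_length(list.files(file.path(dir, "images")), 5)
  expect_length(list.files(file.path(dir, "markers")), 5)
  expect_length(list.files(file.path(dir, "classmaps")), 5)
  pts <- readAnnotations(file.path(dir, "points.csv"), "points")
  truth <- utils::read.csv(file.path(dir, "truth.csv"))
  expect_equal(vapply(pts[truth$image_id], function(p) nrow(p@points),
                      integer(1)),
               stats::setNames(truth$count, truth$image_id))
  # class-map codes round-trip through PNG
  cm <- png::readPNG(file.path(dir, "classmaps", "scene_001.png"))
  scene1 <- generateScenes(5, tinyScene(64), seed = 9L)[[1]]
  codes <- c(soil = 1, shadow = 2, foliage = 3, tassel = 4)
  expect_identical(matrix(names(codes)[round(cm * 255)], nrow(cm)),
                   scene1@classMap)
  # refuses to clobber, reproduces manifests under the same seed
  expect_error(generateDataset(5, dir, config = tinyScene(64), seed = 9L),
               "not empty")
  dir2 <- withr::local_tempdir()
  man2 <- generateDataset(5, dir2, config = tinyScene(64), seed = 9L)
  expect_identical(man, man2)
})

test_that("the 80/20 split reproduces the published 258/65 partition", {
  ids <- sprintf("img_%03d", 1:323)
  sp <- splitIds(ids, 0.8, seed = 3L)
  expect_length(sp$train, 258)
  expect_length(sp$test, 65)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_identical(sp, splitIds(ids, 0.8, seed = 3L))
})
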