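test_that("channel normalization divides by 255", {
  nc <- normalizeChannels(onePixel(51, 102, 204))
  expect_equal(c(nc@rStar, nc@gStar, nc@bStar), c(0.2, 0.4, 0.8))
  nc0 <- normalizeChannels(onePixel(0, 0, 0))
  expect_equal(c(nc0@rStar, nc0@gStar, nc0@bStar), c(0, 0, 0))
  ncr <- normalizeChannels(onePixel(255, 0, 0))
  expect_equal(c(ncr@rStar, ncr@gStar, ncr@bStar), c(1, 0, 0))
})

test_that("raw index values reproduce the worked examples", {
  raw <- function(r, g, b, idx, v = "prose")
    colorIndex(onePixel(r, g, b), idx, v)@values[1, 1]
  # ExG: pure green maximal, gray neutral, soil-like balanced
  expect_equal(raw(0, 255, 0, "exg"), 2)
  expect_equal(raw(255, 255, 255, "exg"), 0)
  expect_equal(raw(120, 90, 60, "exg"), 0)
  # ExR: pure red maximal, pure green minimal, white 0.4
  expect_equal(raw(255, 0, 0, "exr"), 1.4)
  expect_equal(raw(0, 255, 0, "exr"), -1)
  expect_equal(raw(255, 255, 255, "exr"), 0.4)
  # tassel index: yellow maximal, blue minimal; tassel scores above foliage
  expect_equal(raw(255, 255, 0, "tassel"), 16)
  expect_equal(raw(0, 0, 255, "tassel"), -1)
  tasselRaw <- raw(200, 180, 80, "tassel")
  foliageRaw <- raw(50, 140, 40, "tassel")
  expect_equal(tasselRaw, (2 * (380 / 255))^2 - 80 / 255, tolerance = 1e-12)
  expect_equal(tasselRaw, 8.5690, tolerance = 1e-4)
  expect_equal(foliageRaw, 2.0638, tolerance = 1e-4)
  expect_gt(tasselRaw, foliageRaw)
  # compact variant parses (2G* + R*)^2 - B*
  expect_equal(raw(50, 140, 40, "tassel", "compact"),
               (2 * 140 / 255 + 50 / 255)^2 - 40 / 255, tolerance = 1e-12)
})

test_that("rescaling maps the theoretical range onto [0, 255]", {
  mkIdx <- function(v, nm, v2 = "prose") {
    rng <- tasselcount:::indexRange(nm, v2)
    new("IndexMap", values = matrix(v), indexName = nm, variant = v2,
        rangeMin = rng[1], rangeMax = rng[2])
  }
  expect_equal(rescaleIndex(mkIdx(2, "exg"))@values[1], 255)
  expect_equal(rescaleIndex(mkIdx(-2, "exg"))@values[1], 0)
  expect_equal(rescaleIndex(mkIdx(0, "exg"))@values[1], 127.5)
  expect_equal(pixelScore(200, 180, 80, "tassel"), 143.54, tolerance = 1e-3)
  expect_equal(pixelScore(50, 140, 40, "tassel"), 45.96, tolerance = 1e-3)
  expect_equal(pixelScore(120, 90, 60, "exg"), 127.5)
  expect_equal(pixelScore(50, 140, 40, "exg"), 175)
  expect_equal(pixelScore(200, 180, 80, "exg"), 147.5)
  expect_error(tasselcount:::indexRange("bogus"), "unknown index")
})

test_that("all indices match a per-pixel brute-force oracle on a color cube", {
  lv <- seq(0L, 255L, by = 17L)  # 16 levels per channel
  grid <- expand.grid(r = lv, g = lv, b = lv)
  H <- 64L; W <- 64L  # 4096 pixels
  img <- rgbImage(array(c(grid$r, grid$g, grid$b), c(H, W, 3)), "cube")
  nc <- normalizeChannels(img)
  for (idx in c("exg", "exr", "tassel")) {
    got <- rescaleIndex(colorIndex(nc, idx))@values
    want <- matrix(rescaleOracle(
      mapply(rawIndexOracle, grid$r, grid$g, grid$b,
             MoreArgs = list(indexName = idx)), idx), H, W)
    expect_lt(max(abs(got - want)), 1e-9)
  }
})

test_that("threshold masks use >=-survives semantics and nest", {
  rng <- tasselcount:::indexRange("exg")
  ridx <- new("RescaledIndexMap",
              values = matrix(c(131, 130.999, 0, 255), 2, 2),
              indexName = "exg", variant = "prose",
              rangeMin = rng[1], rangeMax = rng[2])
  m <- thresholdMask(ridx, 131)
  expect_identical(maskKeep(m), matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2))
  expect_true(all(maskKeep(thresholdMask(ridx, 0))))
  expect_false(any(maskKeep(thresholdMask(ridx, 256))))
  expect_error(thresholdMask(ridx, 257), "\\[0, 256\\]")
  # nesting: keep(t2) subset of keep(t1) for t1 <= t2
  img <- randomImage(3, 12, 12)
  r <- rescaleIndex(tasselIndex(normalizeChannels(img)))
  ts <- sort(runif(6, 0, 256))
  for (i in seq_len(length(ts) - 1)) {
    k1 <- maskKeep(thresholdMask(r, ts[i]))
    k2 <- maskKeep(thresholdMask(r, ts[i + 1]))
    expect_true(all(k1[k2]))
  }
})

test_that("two-step filter reproduces the worked pixel chain", {
  # soil fails step 1; foliage passes step 1 but fails step 2; tassel passes
  soil <- twoStepFilter(onePixel(120, 90, 60), 131, 90)
  expect_false(soil@step1Mask@keep[1, 1])
  expect_identical(unname(soil@filtered@pixels[1, 1, ]), c(0L, 0L, 0L))
  fol <- twoStepFilter(onePixel(50, 140, 40), 131, 90)
  expect_true(fol@step1Mask@keep[1, 1])
  expect_false(fol@step2Mask@keep[1, 1])
  expect_identical(unname(fol@filtered@pixels[1, 1, ]), c(0L, 0L, 0L))
  tas <- twoStepFilter(onePixel(200, 180, 80), 131, 90)
  expect_true(tas@step1Mask@keep[1, 1] && tas@step2Mask@keep[1, 1])
  expect_identical(unname(tas@filtered@pixels[1, 1, ]),
                   c(200L, 180L, 80L))
})

test_that("two-step filter honors its boundary identities and mask algebra", {
  img <- randomImage(4, 15, 11)
  keepAll <- twoStepFilter(img, 0, 0)
  expect_identical(pixels(keepAll@filtered), pixels(img))
  none <- twoStepFilter(img, 256, 0)
  expect_true(all(pixels(none@filtered) == 0L))
  # surviving pixels are exactly the intersection of the independent masks
  fr <- twoStepFilter(img, 131, 90)
  nc <- normalizeChannels(img)
  m1 <- maskKeep(thresholdMask(rescaleIndex(excessGreen(nc)), 131))
  m2 <- maskKeep(thresholdMask(rescaleIndex(tasselIndex(nc)), 90))
  expect_identical(maskKeep(fr@step1Mask), m1)
  expect_identical(maskKeep(fr@step2Mask), m2)
  expect_identical(pixels(fr@filtered),
                   pixels(applyMask(img, new("BinaryMask",
                                             keep = m1 & m2))))
})
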