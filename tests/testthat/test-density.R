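test_that("density maps conserve mass, including boundary kernels", {
  empty <- buildDensityMap(new("PointAnnotation", imageId = "e",
                               points = cbind(row = numeric(),
                                              col = numeric())),
                           c(50, 50), 8)
  expect_equal(sum(densityValues(empty)), 0)

  center <- buildDensityMap(new("PointAnnotation", imageId = "c",
                                points = cbind(row = 49.5, col = 49.5)),
                            c(100, 100), 8)
  v <- densityValues(center)
  expect_lt(abs(sum(v) - 1), 1e-6)
  peak <- which(v == max(v), arr.ind = TRUE)
  expect_true(all(peak[, 1] %in% c(50, 51)) && all(peak[, 2] %in% c(50, 51)))

  corner <- buildDensityMap(new("PointAnnotation", imageId = "k",
                                points = cbind(row = c(0, 25),
                                               col = c(0, 25))),
                            c(50, 50), 8)
  expect_lt(abs(sum(densityValues(corner)) - 2), 1e-6)
  expect_error(buildDensityMap(new("PointAnnotation", imageId = "o",
                                   points = cbind(row = 60, col = 5)),
                               c(50, 50), 8), "outside")
})

test_that("density mass is conserved for random point sets", {
  for (i in 1:25) {
    set.seed(i)
    H <- sample(40:90, 1); W <- sample(40:90, 1)
    n <- sample(0:15, 1)
    pts <- new("PointAnnotation", imageId = "r",
               points = cbind(row = runif(n, 0, H - 1),
                              col = runif(n, 0, W - 1)))
    dm <- buildDensityMap(pts, c(H, W), runif(1, 2, 10))
    expect_lt(abs(sum(densityValues(dm)) - n), 1e-6)
  }
})

test_that("patch decomposition enumerates exactly the full-fit windows", {
  mkScene <- function(H, W) {
    rgbImage(array(sample(0:255, H * W * 3, TRUE), c(H, W, 3)), "p")
  }
  cfg <- counterConfig()
  set.seed(20)
  img64 <- mkScene(64, 64)
  dm64 <- buildDensityMap(new("PointAnnotation", imageId = "p",
                              points = cbind(row = 31.5, col = 31.5)),
                          c(64, 64), 8)
  ps <- extractPatches(img64, dm64, cfg)
  expect_equal(nrow(ps@patches), 25L)   # (floor(32/8)+1)^2

  img32 <- mkScene(32, 32)
  dm32 <- buildDensityMap(new("PointAnnotation", imageId = "p",
                              points = cbind(row = 16, col = 16)),
                          c(32, 32), 8)
  one <- extractPatches(img32, dm32, cfg)
  expect_equal(nrow(one@patches), 1L)
  expect_equal(one@targets, sum(densityValues(dm32)))

  img31 <- mkScene(31, 64)
  dm31 <- buildDensityMap(new("PointAnnotation", imageId = "p",
                              points = cbind(row = 10, col = 10)),
                          c(31, 64), 8)
  expect_error(extractPatches(img31, dm31, cfg), "smaller than the patch")
})

test_that("patch counts match brute-force offset enumeration", {
  for (i in 1:50) {
    set.seed(100 + i)
    ps <- sample(8:40, 1)
    stride <- sample(1:ps, 1)
    H <- sample(ps:(ps + 60), 1); W <- sample(ps:(ps + 60), 1)
    off <- tasselcount:::windowOffsets(H, W, ps, stride)
    got <- length(off$rows) * length(off$cols)
    # brute force: count offsets whose window fits
    want <- 0
    for (a in 0:(H - 1)) for (b in 0:(W - 1))
      if (a %% stride == 0 && b %% stride == 0 &&
          a + ps <= H && b + ps <= W) want <- want + 1
    expect_equal(got, want)
    expect_equal(got,
                 (floor((H - ps) / stride) + 1) *
                   (floor((W - ps) / stride) + 1))
  }
})

test_that("patch targets equal direct density sums over footprints", {
  scene <- generateScene(tinyScene(12), "t")
  cfg <- counterConfig(stride = 16L)
  dm <- buildDensityMap(scene@points, dim(scene@classMap), cfg@bandwidth)
  ps <- extractPatches(scene@image, dm, cfg)
  off <- tasselcount:::windowOffsets(nrow(scene@classMap),
                                     ncol(scene@classMap), 32L, 16L)
  k <- 1
  for (a in off$rows) for (b in off$cols) {
    expect_equal(ps@targets[k],
                 sum(densityValues(dm)[(a + 1):(a + 32),
                                       (b + 1):(b + 32)]))
    k <- k + 1
  }
  # patch pixels are the image values scaled to [0, 1]
  first <- array(ps@patches[1, ], c(32, 32, 3))
  expect_equal(first, pixels(scene@image)[1:32, 1:32, ] / 255)
})
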