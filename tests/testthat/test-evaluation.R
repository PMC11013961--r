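test_that("metrics reproduce the hand-worked examples", {
  exact <- countRecords(c("a", "b"), c(10, 20), c(10, 20))
  expect_equal(countMae(exact), 0)
  expect_equal(nmspe(exact), 0)
  expect_equal(predictiveDeviance(exact), 0)

  r <- countRecords(c("a", "b"), c(10, 20), c(8, 25))
  expect_equal(countMae(r), 3.5)
  expect_equal(nmspe(r), (4 / 8 + 25 / 25) / 2)  # 0.75
  expect_equal(countMae(countRecords("a", 7, 0)), 7)
  # denominator floor guards zero predictions
  expect_equal(nmspe(countRecords("a", 3, 0), floor = 0.5), 18)
  # predictive deviance with the observed-zero convention
  expect_equal(predictiveDeviance(countRecords("a", 0, 3)), 6)
  expect_error(countMae(countRecords(character(), integer(), numeric())),
               "at least 1")
})

test_that("correlation metrics handle monotone, reversed and tied inputs", {
  obs <- c(3, 7, 11, 20)
  lin <- countRecords(letters[1:4], obs, 2 * obs + 1)
  expect_equal(spearmanCount(lin), 1)
  expect_equal(rSquaredCount(lin), 1)
  expect_equal(spearmanCount(countRecords(letters[1:4], obs,
                                          max(obs) - obs)), -1)
  expect_equal(spearmanCount(countRecords(letters[1:4], 1:4,
                                          c(1, 3, 2, 4))), 0.8)
  flat <- countRecords(letters[1:3], c(5, 5, 5), c(1, 2, 3))
  expect_error(spearmanCount(flat), class = "tasselcount_degenerate")
  expect_error(rSquaredCount(flat), class = "tasselcount_degenerate")
})

test_that("metrics match independent brute-force implementations", {
  bruteMae <- function(o, p) { s <- 0; for (i in seq_along(o))
    s <- s + abs(o[i] - p[i]); s / length(o) }
  bruteNmspe <- function(o, p, fl = 0.5) { s <- 0
    for (i in seq_along(o)) s <- s + (o[i] - p[i])^2 / max(p[i], fl)
    s / length(o) }
  brutePd <- function(o, p, fl = 0.5) { s <- 0
    for (i in seq_along(o)) {
      ph <- max(p[i], fl)
      lead <- if (o[i] == 0) 0 else o[i] * log(o[i] / ph)
      s <- s + lead - (o[i] - ph)
    }
    2 * s }
  avgRank <- function(x) {  # average ranks computed from scratch
    r <- numeric(length(x))
    for (i in seq_along(x))
      r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
    r
  }
  brutePearson <- function(x, y) {
    n <- length(x)
    sx <- sum(x); sy <- sum(y)
    (n * sum(x * y) - sx * sy) /
      sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
  }
  for (i in 1:100) {
    rec <- randomRecords(500 + i, n = sample(3:20, 1))
    o <- rec$observed; p <- rec$predicted
    expect_lt(abs(countMae(rec) - bruteMae(o, p)), 1e-9)
    expect_lt(abs(nmspe(rec) - bruteNmspe(o, p)), 1e-9)
    expect_lt(abs(predictiveDeviance(rec) - brutePd(o, p)), 1e-9)
    expect_gte(nmspe(rec), 0)
    expect_gte(predictiveDeviance(rec), -1e-12)
    if (stats::sd(o) > 0 && stats::sd(p) > 0) {
      expect_lt(abs(spearmanCount(rec) -
                      brutePearson(avgRank(o), avgRank(p))), 1e-9)
      expect_lt(abs(rSquaredCount(rec) - brutePearson(o, p)^2), 1e-9)
    }
  }
})

test_that("nmspe and deviance vanish only for exact predictions", {
  for (i in 1:20) {
    set.seed(600 + i)
    o <- sample(1:30, 5)
    exact <- countRecords(letters[1:5], o, o)
    expect_equal(nmspe(exact), 0)
    expect_equal(predictiveDeviance(exact), 0)
    off <- countRecords(letters[1:5], o, o + sample(c(-1, 1), 5, TRUE))
    expect_gt(nmspe(off), 0)
    expect_gt(predictiveDeviance(off), 0)
  }
})

test_that("the component counter counts well-separated blobs", {
  # 3 tassel-colored blobs on a foliage background
  H <- 40L; W <- 60L
  px <- array(0L, c(H, W, 3))
  px[, , 1] <- 50L; px[, , 2] <- 140L; px[, , 3] <- 40L
  blob <- function(px, r, c) {
    px[r:(r + 3), c:(c + 3), 1] <- 200L
    px[r:(r + 3), c:(c + 3), 2] <- 180L
    px[r:(r + 3), c:(c + 3), 3] <- 80L
    px
  }
  px <- blob(px, 5, 5); px <- blob(px, 20, 30); px <- blob(px, 30, 50)
  img <- rgbImage(px, "blobs")
  res <- baselineComponentCounter(img, 131, 90, minArea = 12L)
  expect_equal(res$count, 3L)
  expect_equal(nrow(res$boxes@boxes), 3L)
  expect_equal(unname(res$boxes@boxes[1, ]), c(4, 4, 4, 4))
  # min-area dominates
  expect_equal(baselineComponentCounter(img, 131, 90,
                                        minArea = 17L)$count, 0L)
  # an all-black image yields zero
  black <- rgbImage(array(0L, c(10, 10, 3)), "black")
  expect_equal(baselineComponentCounter(black, 131, 90)$count, 0L)
})

test_that("component labeling is 8-connected", {
  keep <- matrix(FALSE, 5, 5)
  keep[1, 1] <- TRUE; keep[2, 2] <- TRUE  # touch diagonally
  keep[5, 5] <- TRUE
  res <- tasselcount:::countComponents(keep, minArea = 1L)
  expect_equal(res$count, 2L)
})

test_that("threshold sweeps identify the argmax with lowest-threshold ties", {
  scenes <- lapply(1:3, function(i) generateScene(tinyScene(50 + i),
                                                  paste0("s", i)))
  imgs <- lapply(scenes, function(s) s@image)
  truth <- vapply(scenes, function(s) nrow(s@points@points), integer(1))

  oracle <- function(img, tasselThreshold)
    truth[[match(imageId(img), vapply(imgs, imageId, character(1)))]]
  sw <- thresholdSweep(oracle, imgs, truth, thresholds = 0:255)
  expect_length(sw@rSquared, 256)
  expect_true(all(sw@rSquared == 1))
  expect_equal(sw@bestThreshold, 0L)  # ties resolve to the lowest

  flat <- thresholdSweep(function(img, t) 7, imgs, truth,
                         thresholds = 0:10)
  expect_true(all(flat@degenerate))
  expect_true(all(flat@rSquared == 0))
  expect_error(thresholdSweep(oracle, imgs, rep(4, 3)),
               class = "tasselcount_degenerate")
})

test_that("sweep r-squared decreases as counter noise grows", {
  set.seed(77)
  truth <- sample(5:30, 10)
  imgs <- lapply(seq_along(truth), function(i)
    randomImage(700 + i, 8, 8, imageId = paste0("n", i)))
  ids <- vapply(imgs, imageId, character(1))
  noisyCounter <- function(noiseSd) function(img, tasselThreshold)
    max(0, truth[match(imageId(img), ids)] + rnorm(1, 0, noiseSd))
  meanR2 <- function(noiseSd) {
    mean(vapply(1:20, function(rep) {
      thresholdSweep(noisyCounter(noiseSd), imgs, truth,
                     thresholds = 0L)@rSquared
    }, numeric(1)))
  }
  expect_gt(meanR2(1), meanR2(8))
  expect_gt(meanR2(8), meanR2(30))
})
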