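# slim architecture for fast tests
testCfg <- function(...) {
  args <- list(convWidths = c(4L, 8L), maxEpochs = 3L, patience = 2L,
               batchSize = 64L)
  override <- list(...)
  args[names(override)] <- override
  do.call(counterConfig, args)
}

# random noise patch set with given targets
noisePatches <- function(seed, n, targets, ps = 32L) {
  set.seed(seed)
  new("TrainingPatchSet",
      patches = matrix(runif(n * ps^2 * 3), n, ps^2 * 3),
      targets = targets, patchSize = ps)
}

test_that("a constant target is learned from pure-noise patches", {
  cfg <- testCfg(learningRate = 1e-3, maxEpochs = 6L, patience = 6L,
                 seed = 21L)
  set <- noisePatches(21, 200, rep(3, 200))
  model <- trainCounter(set, cfg)
  held <- noisePatches(22, 40, rep(3, 40))
  preds <- predictPatchCounts(model, held@patches)
  expect_lt(max(abs(preds - 3)), 0.2 * 3)
})

test_that("early stopping respects patience and the log length", {
  cfg <- testCfg(maxEpochs = 50L, patience = 1L, seed = 23L)
  set <- noisePatches(23, 80, runif(80))  # unlearnable: expect no progress
  model <- trainCounter(set, cfg)
  expect_lt(nrow(model@trainLog), 50L)
  expect_lte(model@bestEpoch, nrow(model@trainLog))
  expect_error(trainCounter(noisePatches(1, 1, 0.5), cfg), "at least 2")
})

test_that("training is deterministic under a fixed seed", {
  cfg <- testCfg(seed = 29L)
  set <- noisePatches(29, 90, runif(90, 0, 2))
  m1 <- trainCounter(set, cfg)
  m2 <- trainCounter(set, cfg)
  expect_identical(m1@params, m2@params)
  expect_identical(m1@trainLog, m2@trainLog)
  probe <- noisePatches(30, 10, rep(0, 10))
  expect_identical(predictPatchCounts(m1, probe@patches),
                   predictPatchCounts(m2, probe@patches))
})

test_that("models persist and reload bit-exactly", {
  cfg <- testCfg(seed = 31L)
  model <- trainCounter(noisePatches(31, 60, runif(60)), cfg)
  dir <- withr::local_tempdir()
  writeCounterModel(model, dir)
  back <- readCounterModel(dir)
  probe <- noisePatches(32, 8, rep(0, 8))
  expect_identical(predictPatchCounts(model, probe@patches),
                   predictPatchCounts(back, probe@patches))
  expect_equal(back@config@convWidths, cfg@convWidths)
  expect_equal(back@trainLog$val_loss, model@trainLog$val_loss)
})

test_that("sliding-window redistribution matches the accumulator oracle", {
  cfg <- counterConfig(convWidths = c(4L, 8L))
  zero <- constantModel(0, cfg)
  img <- randomImage(33, 40, 48)
  res0 <- predictCount(zero, img)
  expect_equal(res0$count, 0)
  expect_true(all(res0$heatmap == 0))

  k <- 2.5
  km <- constantModel(k, cfg)
  # single window: the image count is the window prediction
  img32 <- randomImage(34, 32, 32)
  expect_equal(predictCount(km, img32)$count, k, tolerance = 1e-9)
  # overlapping windows on arbitrary sizes: equality with the direct
  # accumulator simulation (here k * covered_pixels / ps^2)
  for (d in list(c(64, 64), c(40, 56), c(33, 47))) {
    got <- predictCount(km, randomImage(35, d[1], d[2]))
    want <- redistributionOracle(d[1], d[2], 32, 8, k)
    expect_equal(got$count, want, tolerance = 1e-9)
    covered <- got$visitCount > 0
    expect_true(all(got$visitCount[!covered] == 0))
    expect_equal(sum(covered) * k / 32^2, want, tolerance = 1e-9)
  }
  expect_error(predictCount(km, randomImage(36, 20, 40)), "smaller")
})

test_that("bootstrap intervals bracket the mean and degenerate to width 0", {
  scenes <- lapply(1:4, function(i) generateScene(tinyScene(40 + i),
                                                  paste0("b", i)))
  cfg <- testCfg(seed = 43L, maxEpochs = 2L)
  sets <- lapply(scenes[1:2], function(s) {
    dm <- buildDensityMap(s@points, dim(s@classMap), cfg@bandwidth)
    extractPatches(s@image, dm, cfg)
  })
  patches <- combinePatchSets(sets)
  testImgs <- lapply(scenes[3:4], function(s) s@image)
  truth <- vapply(scenes[3:4], function(s) nrow(s@points@points),
                  integer(1))

  bs <- bootstrapMae(patches, testImgs, truth, cfg, nReplicates = 3L,
                     replicateSize = 150L)
  expect_lte(bs$interval[["lo"]], bs$meanMae)
  expect_gte(bs$meanMae, bs$interval[["lo"]])
  expect_lte(bs$meanMae, bs$interval[["hi"]])
  # determinism
  bs2 <- bootstrapMae(patches, testImgs, truth, cfg, nReplicates = 3L,
                      replicateSize = 150L)
  expect_identical(bs$maes, bs2$maes)
  # degenerate mode: identical replicates, zero-width interval
  dg <- bootstrapMae(patches, testImgs, truth, cfg, nReplicates = 3L,
                     resample = FALSE)
  expect_equal(diff(range(dg$maes)), 0)
  expect_equal(unname(diff(dg$interval)), 0)
  expect_error(bootstrapMae(patches, testImgs, truth, cfg,
                            nReplicates = 1L), "at least 2")
})
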