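#' Counting-by-regression configuration
#'
#' Defaults follow the published training protocol (32 x 32 sub-images,
#' stride 8, bandwidth 8 px, learning rate 1e-4, up to 50 epochs with
#' patience 5); the convolutional widths of the four blocks are free
#' parameters.
#'
#' @param patchSize sub-image side length.
#' @param stride sub-image stride.
#' @param bandwidth Gaussian sigma (pixels) for density-map targets.
#' @param learningRate Adam learning rate.
#' @param maxEpochs maximum number of training epochs.
#' @param patience early-stopping patience in epochs.
#' @param batchSize minibatch size.
#' @param validationFraction fraction of patches held out for early
#'   stopping.
#' @param convWidths channel widths of the conv blocks (max-pooling after
#'   every block but the last).
#' @param dropout dropout probability.
#' @param seed seed governing the split, initialization, shuffling and
#'   dropout.
#' @return a [CounterConfig-class].
#' @export
counterConfig <- function(patchSize = 32L, stride = 8L, bandwidth = 8,
                          learningRate = 1e-4, maxEpochs = 50L,
                          patience = 5L, batchSize = 256L,
                          validationFraction = 0.1,
                          convWidths = c(16L, 32L, 64L, 128L),
                          dropout = 0.25, seed = 1L) {
  new("CounterConfig", patchSize = as.integer(patchSize),
      stride = as.integer(stride), bandwidth = bandwidth,
      learningRate = learningRate, maxEpochs = as.integer(maxEpochs),
      patience = as.integer(patience), batchSize = as.integer(batchSize),
      validationFraction = validationFraction,
      convWidths = as.integer(convWidths), dropout = dropout,
      seed = as.integer(seed))
}

#' Train the convolutional count regressor
#'
#' Minimizes the mean absolute error (L1 loss) between patch targets and
#' predictions with Adam. A random `validationFraction` of the patches is
#' held out; training stops after `patience` epochs without improvement of
#' the validation loss, or at `maxEpochs`, and the parameters of the best
#' validation epoch are returned. The network is four 3x3 convolution
#' blocks (batch normalization, ReLU, max-pooling after the first three,
#' dropout) followed by a scalar linear head. Fully deterministic for a
#' fixed seed.
#'
#' @param patchSet a [TrainingPatchSet-class] with at least 2 patches.
#' @param cfg a [CounterConfig-class].
#' @param verbose print per-epoch losses.
#' @return a [CounterModel-class].
#' @export
trainCounter <- function(patchSet, cfg = counterConfig(), verbose = FALSE) {
  stopifnot(is(patchSet, "TrainingPatchSet"))
  n <- nrow(patchSet@patches)
  if (n < 2L) stop("need at least 2 training patches")
  if (patchSet@patchSize != cfg@patchSize)
    stop("patch set and config disagree on patchSize")
  withSeed(cfg@seed, {
    nval <- max(1L, round(cfg@validationFraction * n))
    if (nval >= n) nval <- n - 1L
    vi <- sample.int(n, nval)
    fit <- cnnTrainCpp(patchSet@patches[-vi, , drop = FALSE],
                       patchSet@targets[-vi],
                       patchSet@patches[vi, , drop = FALSE],
                       patchSet@targets[vi],
                       cfg@convWidths, cfg@patchSize, cfg@learningRate,
                       cfg@maxEpochs, cfg@patience, cfg@batchSize,
                       cfg@dropout, verbose)
    new("CounterModel", config = cfg, params = fit$params,
        trainLog = data.frame(epoch = seq_along(fit$train_loss),
                              train_loss = fit$train_loss,
                              val_loss = fit$val_loss),
        bestEpoch = as.integer(fit$best_epoch))
  })
}

#' Predict local counts for flattened patches
#'
#' Raw network outputs clamped at 0 from below (counts are non-negative).
#'
#' @param model a [CounterModel-class].
#' @param patches N x (patchSize^2 * 3) matrix, values in \[0, 1\].
#' @return numeric vector of non-negative local counts.
#' @export
predictPatchCounts <- function(model, patches) {
  stopifnot(is(model, "CounterModel"))
  pmax(0, as.numeric(cnnPredictCpp(model@params, patches,
                                   model@config@patchSize, 512L)))
}

#' Predict the tassel count of an image
#'
#' The image is scanned by a sliding window of the training patch size. Each
#' window's predicted local count is divided by patchSize^2 and uniformly
#' redistributed over the window footprint, while the number of windows
#' covering each pixel is tracked. The final count is the sum over pixels of
#' the redistributed count divided by the per-pixel visit count; the same
#' per-pixel ratio is returned as a density heatmap.
#'
#' @param model a [CounterModel-class].
#' @param img an [RgbImage-class], at least patchSize in both dimensions.
#' @param cfg optional [CounterConfig-class] override (e.g. a different
#'   prediction stride); defaults to the model's training config.
#' @return list with elements `count` (non-negative real), `heatmap`
#'   (H x W density raster), `countSum` and `visitCount` (the
#'   redistribution accumulator).
#' @export
predictCount <- function(model, img, cfg = model@config) {
  stopifnot(is(model, "CounterModel"), is(img, "RgbImage"))
  ps <- cfg@patchSize
  d <- dim(img@pixels)
  off <- windowOffsets(d[1], d[2], ps, cfg@stride)
  X <- patchMatrix(img, ps, cfg@stride)
  pred <- predictPatchCounts(model, X)
  countSum <- matrix(0, d[1], d[2])
  visit <- matrix(0L, d[1], d[2])
  k <- 1L
  for (a in off$rows) {
    for (b in off$cols) {
      ri <- (a + 1):(a + ps); ci <- (b + 1):(b + ps)
      countSum[ri, ci] <- countSum[ri, ci] + pred[k] / ps^2
      visit[ri, ci] <- visit[ri, ci] + 1L
      k <- k + 1L
    }
  }
  heat <- matrix(0, d[1], d[2])
  cov <- visit > 0L
  heat[cov] <- countSum[cov] / visit[cov]
  list(count = sum(heat), heatmap = heat, countSum = countSum,
       visitCount = visit)
}

#' Bootstrap mean absolute error of the counter
#'
#' Draws `nReplicates` bootstrap replicates of `replicateSize` training
#' patches (with replacement), trains a model per replicate, evaluates the
#' MAE on a fixed holdout test set, and summarizes the replicate MAEs by
#' their mean and the 2.5th/97.5th percentile interval. Fully determined by
#' `cfg@seed`. With `resample = FALSE` (a degenerate diagnostic mode) every
#' replicate uses the full patch set and the same seed, so all replicate
#' MAEs coincide and the interval has width 0.
#'
#' @param trainPatches a [TrainingPatchSet-class].
#' @param testImages list of [RgbImage-class] test images.
#' @param testTruth numeric vector of observed counts, aligned with
#'   `testImages`.
#' @param cfg a [CounterConfig-class].
#' @param nReplicates number of bootstrap replicates (>= 2).
#' @param replicateSize patches drawn per replicate (default: the full set).
#' @param resample draw patches with replacement (default TRUE).
#' @return list with `meanMae`, `interval` = c(lo, hi) and the per-replicate
#'   `maes`.
#' @export
bootstrapMae <- function(trainPatches, testImages, testTruth, cfg,
                         nReplicates = 100L, replicateSize = NULL,
                         resample = TRUE) {
  stopifnot(is(trainPatches, "TrainingPatchSet"))
  if (nReplicates < 2L) stop("need at least 2 bootstrap replicates")
  if (length(testImages) != length(testTruth))
    stop("testImages and testTruth must align")
  n <- nrow(trainPatches@patches)
  if (is.null(replicateSize)) replicateSize <- n
  seeds <- deriveSeeds(cfg@seed, nReplicates)
  if (!resample) seeds <- rep(seeds[1], nReplicates)
  maes <- vapply(seq_len(nReplicates), function(r) {
    cfgR <- cfg
    cfgR@seed <- seeds[r]
    idx <- if (resample)
      withSeed(seeds[r] + 1L, sample.int(n, replicateSize, replace = TRUE))
    else seq_len(n)
    sub <- new("TrainingPatchSet",
               patches = trainPatches@patches[idx, , drop = FALSE],
               targets = trainPatches@targets[idx],
               patchSize = trainPatches@patchSize)
    model <- trainCounter(sub, cfgR)
    preds <- vapply(testImages,
                    function(im) predictCount(model, im, cfgR)$count,
                    numeric(1))
    mean(abs(testTruth - preds))
  }, numeric(1))
  qs <- unname(stats::quantile(maes, c(0.025, 0.975)))
  list(meanMae = mean(maes), interval = c(lo = qs[1], hi = qs[2]),
       maes = maes)
}

#' Persist a trained counter model
#'
#' Writes a directory holding a JSON manifest (architecture, config,
#' training log) and a binary parameter blob (RDS), so the model reloads
#' bit-exactly.
#'
#' @param model a [CounterModel-class].
#' @param dir destination directory (created if absent).
#' @return the directory, invisibly.
#' @export
writeCounterModel <- function(model, dir) {
  stopifnot(is(model, "CounterModel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- model@config
  manifest <- list(
    class = "CounterModel",
    config = list(patchSize = cfg@patchSize, stride = cfg@stride,
                  bandwidth = cfg@bandwidth,
                  learningRate = cfg@learningRate,
                  maxEpochs = cfg@maxEpochs, patience = cfg@patience,
                  batchSize = cfg@batchSize,
                  validationFraction = cfg@validationFraction,
                  convWidths = cfg@convWidths, dropout = cfg@dropout,
                  seed = cfg@seed),
    bestEpoch = model@bestEpoch,
    trainLog = model@trainLog)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  saveRDS(model@params, file.path(dir, "params.rds"))
  invisible(dir)
}

#' Reload a persisted counter model
#'
#' @param dir directory written by [writeCounterModel()].
#' @return a [CounterModel-class].
#' @export
readCounterModel <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  params <- readRDS(file.path(dir, "params.rds"))
  cfgl <- man$config
  cfg <- counterConfig(patchSize = cfgl$patchSize, stride = cfgl$stride,
                       bandwidth = cfgl$bandwidth,
                       learningRate = cfgl$learningRate,
                       maxEpochs = cfgl$maxEpochs, patience = cfgl$patience,
                       batchSize = cfgl$batchSize,
                       validationFraction = cfgl$validationFraction,
                       convWidths = cfgl$convWidths,
                       dropout = cfgl$dropout, seed = cfgl$seed)
  new("CounterModel", config = cfg, params = params,
      trainLog = as.data.frame(man$trainLog),
      bestEpoch = as.integer(man$bestEpoch))
}
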