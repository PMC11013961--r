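#' Run the full synthetic pipeline end to end
#'
#' Generates a seeded synthetic dataset, filters the test images with the
#' two-step filter, trains the counting-by-regression model on the training
#' split, predicts counts on the test split, evaluates the count-accuracy
#' metrics, and (optionally) sweeps the baseline component counter over
#' step-2 thresholds. All artifacts, the effective configuration and a
#' machine-readable summary JSON are written under `outDir`; two runs with
#' the same seed produce identical summaries.
#'
#' @param outDir output directory.
#' @param seed master seed for every stage.
#' @param nScenes number of synthetic scenes.
#' @param scene template [SceneConfig-class].
#' @param counter [CounterConfig-class] for the regressor (its seed slot is
#'   replaced by a derived seed).
#' @param exgThreshold step-1 ExG threshold.
#' @param tasselThreshold step-2 tassel-index threshold; defaults to the
#'   palette's documented optimum.
#' @param doSweep also run the baseline-counter threshold sweep.
#' @param force overwrite a non-empty output directory.
#' @return the summary list, invisibly.
#' @export
runPipeline <- function(outDir, seed = 1L, nScenes = 20L,
                        scene = sceneConfig(),
                        counter = counterConfig(maxEpochs = 8L,
                                                patience = 3L,
                                                convWidths = c(8L, 16L,
                                                               32L, 64L)),
                        exgThreshold = 131,
                        tasselThreshold = NULL,
                        doSweep = FALSE, force = FALSE) {
  if (is.null(tasselThreshold))
    tasselThreshold <- attr(scene@palette, "optimalThreshold") %||% 90
  manifest <- generateDataset(nScenes, file.path(outDir, "data"),
                              config = scene, seed = seed, force = force)
  scenes <- generateScenes(nScenes, scene, seed)
  trainScenes <- scenes[manifest$train]
  testScenes <- scenes[manifest$test]

  filtDir <- file.path(outDir, "filtered")
  dir.create(filtDir, showWarnings = FALSE, recursive = TRUE)
  for (s in testScenes) {
    fr <- twoStepFilter(s@image, exgThreshold, tasselThreshold)
    writeRgbImage(fr@filtered,
                  file.path(filtDir,
                            paste0(s@image@imageId, "_filtered.png")))
  }

  # pixel-sampling elimination rates at the step-1 threshold
  s1 <- testScenes[[1]]
  samples <- extractSamples(s1@markerImage, s1@image)
  exgCurve <- eliminationCurve(samples, s1@image, "exg")
  elim131 <- eliminationAt(exgCurve, round(exgThreshold))

  cfg <- counter
  cfg@seed <- deriveSeeds(seed, 2L)[2L]
  patchSets <- lapply(trainScenes, function(s) {
    dm <- buildDensityMap(s@points, dim(s@classMap), cfg@bandwidth)
    extractPatches(s@image, dm, cfg)
  })
  model <- trainCounter(combinePatchSets(patchSets), cfg)
  writeCounterModel(model, file.path(outDir, "model"))

  preds <- vapply(testScenes,
                  function(s) predictCount(model, s@image)$count,
                  numeric(1))
  truth <- vapply(testScenes, function(s) nrow(s@points@points),
                  integer(1))
  records <- countRecords(names(testScenes), truth, preds)
  utils::write.csv(records, file.path(outDir, "counts.csv"),
                   row.names = FALSE)
  metrics <- countMetrics(records)
  writeMetricsReport(metrics, file.path(outDir, "metrics.json"))

  summary <- list(
    seed = seed, n_scenes = nScenes,
    n_train = length(trainScenes), n_test = length(testScenes),
    exg_threshold = exgThreshold, tassel_threshold = tasselThreshold,
    exg_elimination = as.list(elim131),
    cbr = metrics)

  if (doSweep) {
    sweep <- thresholdSweep(makeBaselineCounter(exgThreshold),
                            lapply(testScenes, function(s) s@image),
                            truth)
    writeSweepResult(sweep, file.path(outDir, "sweep.json"))
    summary$sweep <- list(best_threshold = sweep@bestThreshold,
                          best_r_squared = sweep@bestRSquared)
  }

  summary$config <- list(
    scene = list(height = scene@height, width = scene@width,
                 tassel_range = scene@tasselRange,
                 shadow_fraction = scene@shadowFraction,
                 n_canopies = scene@nCanopies),
    counter = list(patch_size = cfg@patchSize, stride = cfg@stride,
                   bandwidth = cfg@bandwidth,
                   learning_rate = cfg@learningRate,
                   max_epochs = cfg@maxEpochs, patience = cfg@patience,
                   batch_size = cfg@batchSize,
                   validation_fraction = cfg@validationFraction,
                   conv_widths = cfg@convWidths, dropout = cfg@dropout,
                   seed = cfg@seed))
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
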