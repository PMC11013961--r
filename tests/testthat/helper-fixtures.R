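# shared fixtures, all built in code

# single-pixel image of one color
onePixel <- function(r, g, b) {
  rgbImage(array(c(r, g, b), c(1, 1, 3)), "px")
}

# rescaled score of one color under one index
pixelScore <- function(r, g, b, indexName, variant = "prose") {
  rescaleIndex(colorIndex(onePixel(r, g, b), indexName, variant))@values[1, 1]
}

# seeded random 8-bit image
randomImage <- function(seed, H = 16, W = 20, imageId = "rand") {
  set.seed(seed)
  rgbImage(array(sample(0:255, H * W * 3, replace = TRUE), c(H, W, 3)),
           imageId)
}

# independent scalar-loop oracle for the raw indices
rawIndexOracle <- function(r, g, b, indexName, variant = "prose") {
  rs <- r / 255; gs <- g / 255; bs <- b / 255
  switch(indexName,
         exg = 2 * gs - rs - bs,
         exr = 1.4 * rs - gs,
         tassel = if (variant == "prose") (2 * (gs + rs))^2 - bs
                  else (2 * gs + rs)^2 - bs)
}

rescaleOracle <- function(raw, indexName, variant = "prose") {
  rng <- switch(indexName, exg = c(-2, 2), exr = c(-1, 1.4),
                tassel = if (variant == "prose") c(-1, 16) else c(-1, 9))
  (raw - rng[1]) / (rng[2] - rng[1]) * 255
}

# a CounterModel whose prediction is the constant k for any input
constantModel <- function(k, cfg = counterConfig()) {
  cin <- 3L
  blocks <- lapply(cfg@convWidths, function(cout) {
    blk <- list(W = matrix(0, 9 * cin, cout), gamma = rep(0, cout),
                beta = rep(0, cout), rmean = rep(0, cout),
                rvar = rep(1, cout))
    cin <<- cout
    blk
  })
  npool <- length(cfg@convWidths) - 1L
  D <- (cfg@patchSize / 2^npool)^2 * cfg@convWidths[length(cfg@convWidths)]
  new("CounterModel", config = cfg,
      params = list(blocks = blocks, head_w = rep(0, D), head_b = k),
      trainLog = data.frame(epoch = 1L, train_loss = 0, val_loss = 0),
      bestEpoch = 1L)
}

# direct accumulator simulation of sliding-window count redistribution
redistributionOracle <- function(H, W, ps, stride, windowPred) {
  countSum <- matrix(0, H, W)
  visit <- matrix(0, H, W)
  for (a in seq(0, H - ps, by = stride)) {
    for (b in seq(0, W - ps, by = stride)) {
      ri <- (a + 1):(a + ps); ci <- (b + 1):(b + ps)
      countSum[ri, ci] <- countSum[ri, ci] + windowPred / ps^2
      visit[ri, ci] <- visit[ri, ci] + 1
    }
  }
  covered <- visit > 0
  sum(countSum[covered] / visit[covered])
}

# small record-set fixture generator
randomRecords <- function(seed, n = 10) {
  set.seed(seed)
  countRecords(sprintf("img%02d", seq_len(n)),
               observed = sample(0:40, n, replace = TRUE),
               predicted = round(runif(n, 0, 40), 3))
}

# tiny scene config for fast tests
tinyScene <- function(seed, nTassels = NA_integer_, height = 64L,
                      width = 96L) {
  sceneConfig(height = height, width = width, nTassels = nTassels,
              tasselRange = c(3L, 8L), nCanopies = 3L, seed = seed)
}
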