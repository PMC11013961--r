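---
title: "Methods: two-step tassel filtering and counting by regression"
author: "tasselcount"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-step tassel filtering and counting by regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tasselcount)
```

## The problem

Plot-level aerial (UAV) images of maize trials mix four visual classes:
brownish soil, dark shadows, green foliage, and yellowish tassels. Tassel
counts per plot are a proxy for male flowering and are wanted for hundreds
of plots per flight, so they must be extracted automatically. `tasselcount`
implements two cooperating pieces of machinery:

1. a **two-step color-index filter** that blacks out pixels unlikely to be
   tassel, and the **pixel-sampling** procedure used to choose and justify
   its thresholds; and
2. a **counting-by-regression (CBR)** engine that predicts per-image tassel
   counts from local density regression, plus the **evaluation** machinery
   (MAE, NMSPE, predictive deviance, Spearman correlation, r² threshold
   sweeps, bootstrap intervals) used to compare counting approaches.

A seeded synthetic scene generator supplies images with exact ground truth,
so every component is testable without any external download.

## The two-step filter

All indices operate on channels normalized to $[0,1]$:
$R^* = R/255$, etc.

* **Step 1 — Excess Green (ExG)**: $2G^* - R^* - B^*$, theoretical range
  $[-2, 2]$. High for green vegetation; thresholding it removes soil and
  shadow. The default threshold after rescaling is 131.
* **Step 2 — tassel index**: $(2(G^* + R^*))^2 - B^*$, theoretical range
  $[-1, 16]$. Combines red and green, doubles, squares, and subtracts
  blue, so yellowish pixels (high red and green, low blue) score highest;
  thresholding it separates tassels from foliage. The printed form of this
  formula is typographically ambiguous; the implementation follows its
  verbal description, and the alternative reading $(2G^* + R^*)^2 - B^*$
  (range $[-1, 9]$) is available as `variant = "compact"` for comparison.
* **Excess Red (ExR)**: $1.4R^* - G^*$, range $[-1, 1.4]$, provided as a
  comparison index for the same role as the tassel index.

Raw scores are rescaled linearly from the index's *fixed theoretical
range* onto $[0, 255]$. Per-image min–max rescaling would make one
threshold mean different things on different images; a fixed mapping is
the only convention under which a single threshold (131, or the 90–110
band for step 2) is coherent across thousands of plot images. Rescaled
scores stay floating-point; a pixel survives when its score is **greater
than or equal to** the threshold (the elimination rule "below the
threshold is eliminated" leaves the equality case to convention; we chose
survival at equality). Threshold 0 keeps everything and threshold 256
eliminates everything, so sweep curves include both endpoints.

Step 2 is always computed from the *original* pixel values. Blacked-out
step-1 pixels would score $-1$ (pure black) and be eliminated anyway, but
computing both masks independently makes the filter order-free and each
mask auditable on its own; the filtered image is the intersection of both
masks with eliminated pixels set to $(0,0,0)$.

## Pixel sampling and elimination curves

To choose thresholds, sample pixels of known class are marked on copies of
real images in four pure colors (soil blue, shadow green, foliage red,
tassel yellow). `extractSamples()` recovers the marked coordinates
(exact color match by default; a per-channel tolerance is available for
hand-marked data, and a coordinate matching two classes is rejected), and
`eliminationCurve()` tabulates, for every integer threshold 0..256, the
fraction of each class's sampled pixels that the filter would eliminate.
A good step-2 threshold band eliminates nearly all foliage while sparing
most tassel pixels; `separationBand()` computes that band (at the
conventional 95% / 20% levels) for synthetic scenes, where the class of
every pixel is known.

## Counting by regression

The CBR engine follows the local-count regression design of TasselNet:

1. **Density map.** Each annotated tassel center contributes a bivariate
   Gaussian of standard deviation `bandwidth` (default 8 px), evaluated on
   the pixel grid, truncated at 4 bandwidths and at the image border, and
   renormalized to unit mass. Total mass therefore equals the tassel count
   exactly — truncation at borders loses no mass. The published protocol
   states "bandwidth 8" without units or definition; we interpret it as
   the Gaussian sigma in pixels.
2. **Sub-image decomposition.** The image is cut into overlapping
   32×32 patches at stride 8 (all offsets keeping the window fully inside
   the image; no padding). Each patch's regression target $T_j$ is the
   density-map sum over its footprint, i.e. the expected local count.
3. **Regressor.** A small convolutional network maps a 32×32×3 patch
   (pixel values scaled to $[0,1]$; no mean subtraction, the simplest
   normalization consistent with 8-bit input) to one real number: four
   3×3 convolution blocks with batch normalization and ReLU (channel
   widths 16/32/64/128 by default, configurable), 2×2 max-pooling after
   the first three blocks, one dropout layer (p = 0.25) after the final
   block, and a scalar linear head. Dropout is deliberately placed *after*
   the last batch-normalized block: dropout feeding a batch-normalized
   layer inflates train-time batch variance, so the running statistics
   used at evaluation misnormalize — we observed validation loss rising
   while training loss fell until the dropout layer was moved behind the
   last normalization.
4. **Training.** L1 loss $\frac{1}{M_{tr}}\sum_j |T_j - \hat T_j|$,
   Adam at learning rate $10^{-4}$, minibatches of 256, at most 50 epochs
   with early stopping (patience 5) on a random 10% patch-level validation
   split; the parameters of the best validation epoch are kept. The head
   bias is initialized to the mean training target and the head weights
   are damped (a tenth of the He scale), so optimization starts close to
   the constant predictor instead of from large random outputs. All randomness (split, initialization,
   shuffling, dropout) derives from one seed and training is
   single-threaded and deterministic: the same seed reproduces identical
   parameters.
5. **Prediction.** The image is scanned by the same sliding window; each
   window's predicted count (clamped at 0 — counts cannot be negative) is
   divided by $32^2$ and redistributed uniformly over its footprint while
   a per-pixel visit counter is tracked. The final count is
   $\sum_{x,y} C(x,y)/P(x,y)$ with $C$ the accumulated redistributed count
   and $P$ the visit count; the per-pixel ratio is the density heatmap.
   $P$ enters as a normalizer: a window prediction spread over $n$
   overlapping windows must be counted once, not $n$ times. For a model
   that predicts the constant $k$ this sum equals
   $k \cdot (\text{covered pixels})/32^2$ — the correct count for a
   uniform density of $k$ per window area (it reduces to $k$ exactly when
   the window covers the whole image).
6. **Bootstrap uncertainty.** `bootstrapMae()` redraws training patches
   with replacement, retrains per replicate, evaluates the MAE on a fixed
   holdout set, and reports the replicate mean with the 2.5th/97.5th
   percentile interval. A degenerate mode (no resampling, shared seed)
   yields identical replicates and a zero-width interval, which is used
   to validate the machinery.

## Evaluation metrics

For observed counts $T_k$ and predictions $\hat T_k$ over $M_{ts}$ test
images:

* **MAE** $= \frac{1}{M_{ts}}\sum_k |T_k - \hat T_k|$.
* **NMSPE** $= \frac{1}{M_{ts}}\sum_k (T_k - \hat T_k)^2/\hat T_k$, a
  Chi-squared-like fit statistic for counts.
* **Predictive deviance**
  $= 2\sum_k [T_k \log(T_k/\hat T_k) - (T_k - \hat T_k)]$, the Poisson
  deviance form; the leading term is 0 when $T_k = 0$.
* **Spearman** rank correlation (average ranks on ties) and **r²**, the
  squared Pearson correlation of observed versus predicted (not the
  regression-through-origin variant, which the source protocol does not
  specify).

NMSPE divides by $\hat T_k$ and the deviance takes its logarithm, and a
counter can legitimately predict 0; both therefore floor the prediction at
a configurable 0.5 counts (half the smallest nonzero count). Only the
observed-zero convention is prescribed by the protocol; the floor is this
package's guard, exposed as an argument.

`thresholdSweep()` evaluates a counter on test images filtered at every
step-2 threshold 0..255 (step 1 held fixed) and records the r² curve and
its argmax, with ties resolved to the lowest threshold. Thresholds where
predictions are constant — e.g. everything filtered away near threshold
255 — are recorded as r² = 0 with a `degenerate` flag rather than NA so
curves stay plottable. The sweep accepts any counter of the form
`function(img, tasselThreshold)`; `makeBaselineCounter()` supplies a
detector-free stand-in that labels the surviving filter mask with
8-connected components and counts components of at least `minArea` pixels
(default 12, a plausible tassel footprint at plot-crop resolution; both
exposed). Training an actual object detector is out of scope — the sweep
machinery is detector-agnostic by design.

## The synthetic scene generator

`generateScene()` renders scaled-down plot crops (default 128×256) with:
soil background; elliptical foliage canopies, each with its own brightness
offset (±6) plus per-pixel jitter (±2); dark elliptical shadows (~12%
cover); and 5–25 branched tassel glyphs (five 7-px branches fanning
upward, 2 px thick) drawn last with no blur, at centers kept at least
2·(branch length + 2) px apart. The palette is chosen so the filter
assumptions hold *by construction*:

* soil (120,90,60) has rescaled ExG exactly 127.5 and jitter ±3 cannot
  reach 131 — every soil pixel is eliminated in step 1;
* shadow (40,40,45) is far below the ExG threshold;
* foliage (50,140,40) passes step 1 (ExG 175) but cannot exceed a
  rescaled tassel score of about 53 under its jitters;
* tassel (200,180,80) passes both (ExG ≈ 147.5, tassel ≈ 143.5, never
  below about 129 under jitter ±10).

This yields a documented step-2 separation gap (roughly 53–129 for the
default palette; `separationBand()` measures it empirically per scene
set) containing the documented optimal threshold 90. Each scene carries a
per-pixel class map and a marker image, so pixel-sampling runs end to end
on synthetic data. `checkSeparationContract()` verifies the contract on
every generated scene and names the violating class if a custom palette
breaks it.

The per-canopy brightness offset matters for the threshold sweep: foliage
is then eliminated canopy by canopy as the threshold rises, so partially
filtered canopies remain large connected blobs and the component counter
only becomes exact once the last canopy clears — which places the r²
argmax inside the separation band instead of at an accidental lower
threshold where scattered surviving pixels happen to fall below the
minimum component area.

What the generator does *not* emulate: perspective, blur and chromatic
noise of real optics, overlapping/occluded tassels, debris, growth-stage
and genotype variation, or lighting gradients. Passing tests on synthetic
scenes therefore validates the *procedures* (arithmetic, conservation,
separation logic, training mechanics), not field-level accuracy; the
published headline numbers (r² ≈ 0.70, MAE ≈ 8) come from a private
323-image UAV dataset and are not reproducible here.

## Numerical choices and degenerate inputs

* Kernels truncated at 4σ: the omitted tail is < 1e-7 of the mass and
  renormalization makes conservation exact to < 1e-6 per map.
* Rescaled scores are never quantized to integers; sweep and elimination
  curves evaluate strict `< t` / `>= t` comparisons on floats.
* Images smaller than the patch size are rejected (no padding); a 31×64
  image is an error, not an empty patch set.
* Zero-variance truth or predictions raise a classed error
  (`tasselcount_degenerate`) for correlation metrics, and record r² = 0
  with a flag inside sweeps.
* Empty record sets, empty training sets, fewer than 2 bootstrap
  replicates, and annotation coordinates outside image bounds are all
  validation errors.

## Desk-scale protocol sizes

The package's own verification protocol (tests and the acceptance script)
runs at desk scale, chosen as the smallest sizes at which the counting
signal is clearly learnable: 60 scenes of 128×256 (48 train / 12 test,
about 18k training patches), conv widths 8/16/32/64, at most 10 epochs;
bootstrap demonstrations use 10 replicates on small scenes. The full
published protocol (323 plot images, about 1000K sub-images, 50 epochs,
100 bootstrap replicates of 250K patches) is what the defaults encode;
the engine is the same.

## Known limitations

* The regressor is a from-scratch implementation tuned for clarity and
  determinism, not throughput; GPU training and very large patch sets are
  out of scope.
* The baseline component counter is a stand-in for a trained detector:
  adequate on synthetic scenes where tassels are separated blobs, but not
  a detector for real imagery.
* JPEG input is accepted read-only; all quantitative work should use PNG,
  for which I/O is bit-exact.
* Fixed thresholds are global per run; adaptive per-image thresholding is
  deliberately not implemented.
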