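---
title: "Detecting individual tomato fruits in flash-lit canopy images"
author: "tomascan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting individual tomato fruits in flash-lit canopy images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(tomascan)
```

## The problem

Counting tomato fruits on the plant — including the small, green *young*
fruits that drive long-term yield forecasts — is hard to automate with
fixed color or size thresholds, because the thresholds that work for one
image fail for the next. The approach implemented here replaces
thresholds with learned classifiers at two levels, and adds a third,
geometric stage to split touching fruits apart:

1. **Pixel-based segmentation.** Every pixel is described by 15 color
   features spanning five color spaces — normalized chromaticity
   $(r, g, b)$, HSV, CIELAB $(L^\*, a^\*, b^\*)$, CIELUV
   $(L^\*, u^\*, v^\*)$ and YCbCr — and a CART decision tree assigns it
   to fruit, leaf, stem or background.
2. **Blob-based false-positive elimination.** 8-connected components of
   fruit pixels, cropped by their minimal enclosing rectangles
   ("blobs"), are summarised by 19 features (the mean of each color
   feature over the blob's member pixels, the gray-level histogram
   contrast, the GLCM angular second moment, the blob size
   $w \times h$, and the aspect ratio $w / h$) and classified by a
   random forest into multi-fruit, single-fruit and non-fruit blobs.
   Non-fruit blobs — overwhelmingly few-pixel speckles from pixel-stage
   misclassification — are dropped.
3. **Individual fruit localization.** A single-fruit blob's position is
   its mask center of gravity. A multi-fruit blob (a truss of touching
   fruits) is resolved through the flash highlights: each fruit carries
   one small overexposed spot, which scores high on the map
   $V \cdot (1 - S)$ built from the HSV value and inverted saturation
   channels. X-means clustering of the map values over the blob's
   pixels isolates the brightest cluster, and each surviving connected
   highlight region contributes one detection at its centroid.

Detections are matched one-to-one to ground-truth fruits (greedy, by
increasing distance, a detection being eligible for a fruit when it
falls inside that fruit's disk) and scored by

$$\mathrm{recall} = \frac{\text{matched fruits}}{\text{all fruits}},
\qquad
\mathrm{precision} = \frac{\text{matched detections}}{\text{all detections}},$$

with recall additionally stratified by growth stage (young, immature,
mature).

## Color conventions

The method itself fixes no color conventions, so the package pins them
explicitly: sRGB primaries and the D65 white point for CIELAB and
CIELUV (via `grDevices::convertColor()`); BT.601 full-range YCbCr on
the $[0, 255]$ scale; hue in degrees $[0, 360)$, defined as 0 for
achromatic pixels; normalized chromaticity defined as $1/3$ per channel
at black so $r + g + b = 1$ holds everywhere. All conversions run in
double precision with no intermediate 8-bit re-quantization. Exact
numeric agreement with any particular conversion library is therefore
not claimed — only convention-documented equivalence.

## X-means details

`xmeans_1d()` starts from one cluster and repeatedly offers every
cluster a 2-means split, accepting the split when the two-cluster BIC
of that cluster's points exceeds the one-cluster BIC; ties break toward
fewer clusters, which biases against over-counting fruits. A global
Lloyd refinement runs between split rounds. Degenerate inputs (constant
values, clusters below the minimum split size) can never justify a
split.

The BIC is the hard-assignment spherical-Gaussian likelihood with
*per-cluster* maximum-likelihood variances and mixing weights $n_j/n$
(free parameters $3K - 1$ in one dimension), with three numerical
safeguards that the desk-scale simulations showed to be necessary
rather than cosmetic:

* **Per-cluster rather than pooled variances.** Under the pooled
  variance $\hat\sigma^2 = \mathrm{SSE}/(n-K)$ the split test provably
  rejects the top-level split of four or more equally spaced
  components — no 2-cut of five 100-point components at $10\sigma$
  separation beats the one-cluster BIC — so cluster counts above three
  are never reached. Per-cluster variances restore the gain; the
  mixing-entropy term still keeps single Gaussians whole.
* **A variance floor** at 0.1% of the overall spread, fixed once at
  the root: per-cluster MLE variances otherwise diverge on a handful
  of near-identical (e.g. 8-bit-quantized) values, shattering tight
  highlight clusters into micro-fragments.
* **Deterministic cut search with an outlier-peeling guard.** In one
  dimension every 2-partition is an order cut, so each split scores
  two deterministic proposals by BIC — the exact SSE-optimal 2-means
  cut (prefix-sum scan) and the largest-gap cut, which never bisects a
  well-separated component — and both children must hold at least 10
  points. Without the size guard, isolating two stray tail points
  passes the BIC test by shrinking the sibling's variance, and the
  stray center then captures half of a genuine component during the
  global refinement pass.

With these choices the procedure is fully deterministic and recovers
the true component count in 100/100 seeded mixtures for each
$k \in \{1, 2, 3, 5\}$ at $10\sigma$ separation.

Two localization knobs matter:

* `min_region` (default 5 px) — the minimum highlight-component size;
  it suppresses single-pixel glints. The method's source gives no
  value, so it is configuration surface.
* `kmax` (default 20) — an upper bound on clusters per blob, generously
  above any plausible truss size.

Clustering uses the map values of the blob's *member* pixels only, not
the whole rectangle; background highlights inside the bounding box (the
classic shiny-pole failure of highlight-based detection) therefore
cannot contaminate the clusters.

## What the synthetic scene generator emulates

No labeled greenhouse imagery accompanies the method, so the package
generates its own study conditions: flash-lit nighttime canopy scenes
with exact per-pixel ground truth. `scene_config()` defaults define
those conditions; they were chosen once, on first principles, and the
tests run against them:

* **Geometry.** Fruits are disks with mild Lambertian-style radial
  shading; leaves are rotated ellipses; stems are thin, wavy vertical
  strips. A 320 x 240 canvas holds 2 young, 3 immature and 2 mature
  isolated fruits plus one truss of 2-4 mutually tangent fruits
  (adjacent disks overlap by 2 px, so each truss is one 8-connected
  fruit region; non-adjacent truss members may touch but not
  interpenetrate, so no fruit covers a neighbor's highlight). Radii
  follow the stage taxonomy: young 4-7 px, immature 9-14 px, mature
  10-16 px.
* **Photometry.** Mature fruits are red (205, 45, 40); immature fruits
  pale green (190, 205, 160); young fruits small and dark green
  (80, 105, 60), deliberately close to the brownish-green stems
  (95, 110, 58) to keep the benchmark's hardest confusion honest. The
  background is near-black (nighttime, flash-lit foreground). Every
  fruit carries one off-center near-white highlight disk (radius 28% of
  the fruit radius, floor 2 px); leaves may carry small specular glints
  (probability 0.3), reproducing the highlight-on-background false-
  positive mode.
* **Sensor model.** Additive Gaussian noise (default sd 2 counts),
  plus impulse ("hot pixel") noise at rate 0.0015 — bright random
  pixels that, together with heavy per-pixel color texture on the stems
  (sd 14), make the pixel stage produce the large candidate-blob counts
  (hundreds per scene) that the blob stage must collapse back to the
  handful of true fruit regions.
* **Occlusion.** With probability `occlusion` per fruit, a leaf ellipse
  is drawn over part of the fruit after it; the class map always
  reflects paint order, so unoccluded fruit pixels are labeled fruit
  exactly.

All randomness flows from one root seed through a documented splitting
scheme (`seed * 1000003 + stream` mod 2147483629), so scenes are
bit-reproducible.

What the generator does **not** emulate: perspective, photorealistic
shading, interreflections, color-calibrated real tomato spectra, depth
variation in fruit size, and motion blur. Passing tests therefore show
that the pipeline's mechanisms work as designed under controlled
conditions — not that the headline numbers would transfer to any
particular greenhouse.

## Training-set construction

* **Pixel training** samples exact per-class counts from ground-truth
  regions across fresh scenes. The reference field scale is 140,000
  fruit and 100,000 per other class; the package's standard desk scale
  is 1/100 of that (1,400 / 1,000). Fruit pixels are drawn per fruit
  rather than uniformly by area: young fruits hold only a few percent
  of the fruit area, and with a CART leaf floor of 50 samples an
  area-uniform draw could never carve a young-fruit leaf. Per-fruit
  sampling emulates an annotator who deliberately clicks fruits of
  every stage.
* **Blob training** harvests candidate blobs from the *pixel
  classifier's own segmentation* of fresh scenes, labeled exactly from
  ground truth (two or more fruit centers inside the blob mask =
  multi-fruit; one = single-fruit; none = non-fruit). Training on
  clean ground-truth blobs instead would present the forest with
  smooth disks whose texture statistics do not match the ragged blobs
  it meets at detection time; with the classifier-in-the-loop
  harvesting, the training and test distributions coincide, which is
  also how the original workflow obtained its blobs. A
  ground-truth-plus-injected-speckles mode remains available when no
  pixel classifier exists yet. The standard counts are the reference
  scale itself (30 multi / 200 single / 2000 non): with a 10x
  scale-down the forest would see only 3 multi-fruit examples and
  essentially never predict that class.

## Classifier settings

The CART pixel tree uses Gini impurity, no cost-complexity pruning
(`cp = 0`), and a minimum leaf size of 50 — a large leaf floor keeps
the tree compact and noise-resistant at the training scales above; no
class reweighting is applied (a `class_weights` knob exists). The blob
forest uses the classical defaults: 500 trees,
$\lfloor\sqrt{19}\rfloor = 4$ features per split, bootstrap sampling;
its mean-decrease-Gini importances are exposed via `tidy()`. On the
synthetic study conditions, blob size ranks at the top of the
importance list — the separation between few-pixel speckles,
single-fruit blobs and multi-fruit trusses is primarily a size effect.

Texture dialect: the GLCM uses 256 gray levels and the single offset
(0, 1) with its symmetric pair, computed over the full rectangular
patch (the crop is what the texture descriptor is defined on);
histogram "contrast" is the variance (second central moment) of the
gray-level distribution, the conventional first-order reading of the
term — mean absolute deviation or range would be defensible
alternatives. Color means, by contrast, are averaged over mask pixels
only, to avoid background bleed; both domains are configurable. Blobs
too small to support a GLCM pair take the constant-texture limits
(ASM 1, contrast as computed).

## A worked run

```{r pipeline, eval = FALSE}
cfg <- run_config(out_dir = tempfile("run"), seed = 1, n_scenes = 5)
cmd_synth(cfg)      # scenes + class maps + fruit CSVs + manifest
cmd_train(cfg)      # pixel CART + blob forest, saved as archives
cmd_detect(cfg)     # per-image detection CSVs + blob-count log
cmd_evaluate(cfg)   # stage-stratified report (JSON + text)
```

The same stages are available as plain functions for interactive work:

```{r interactive, eval = FALSE}
scfg <- scene_config()
px  <- generate_pixel_training_set(
  scfg, c(background = 1000, fruit = 1400, leaf = 1000, stem = 1000),
  seed = 1)
pc  <- train_pixel_classifier(px)
bl  <- generate_blob_training_set(scfg, counts = c(30, 200, 2000),
                                  pixel_classifier = pc, seed = 2)
bc  <- train_blob_classifier(bl$features, bl$features$blob_class)

sc   <- generate_scene(scfg, seed = 99)
dets <- detect_fruits(sc$image, pc, bc)
detection_report(dets, sc$fruits)
```

## Numerical and degenerate-input choices

* Empty images, empty masks, out-of-bounds seed points, dimension
  mismatches and single-class training sets raise classed errors
  rather than returning silently wrong results.
* Undefined metrics (no fruits of a stage; no detections) are reported
  as absent (`NA` / JSON null), never as 0 or 1.
* Vertical part boundaries are half-open, and each fruit belongs to
  the part containing its centroid, so part-wise counts always
  reconcile with whole-image counts. The cut rows themselves are pure
  configuration; the part-by-part protocol prescribes none.
* `detect_fruits()` sorts detections row-major and is deterministic
  given the fitted models and seed; two full pipeline runs from one
  configuration produce byte-identical reports.

## Problem sizes used by the test suite

The suite trains at the desk scales above (pixel 1,400/1,000; blobs
30/200/2000), evaluates 20 held-out scenes for the easy-regime check,
5 scenes per noise level for the degradation check, 50 noiseless truss
fixtures for highlight localization, and 100 seeded mixtures per
component count for the X-means check. These sizes are the package's
chosen study conditions; scaling them up only sharpens the estimates.

## Known limitations

* Fruits lacking any specular highlight inside a multi-fruit blob
  cannot be separated — the cue simply is not there. Flash-lit
  acquisition is assumed.
* Blob size is the forest's dominant feature, so the classifier does
  not transfer across camera distances without rescaling.
* A fruit whose pixels are entirely absorbed into leaf/stem classes at
  stage one is unrecoverable downstream; false-negative recovery is
  out of scope.
* The matching criterion (within-disk, greedy by distance) is the
  evaluation's own convention; the method's source defines none.
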