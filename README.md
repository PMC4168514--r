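# tomascan

Detection of individual tomato fruits — mature, immature and *young* —
in RGB images of greenhouse canopies taken with on-camera flash.
Threshold-free: both segmentation stages are learned classifiers, so no
per-image color/size cutoffs need tuning.

The pipeline has three stages:

1. **Pixel-based segmentation.** Each pixel is described by 15 color
   features across five color spaces — chromaticity (r, g, b), HSV,
   CIELAB (L\*, a\*, b\*), CIELUV (L\*, u\*, v\*), YCbCr — and labeled
   fruit / leaf / stem / background by a CART decision tree.
2. **Blob-based false-positive elimination.** 8-connected fruit-pixel
   components ("blobs", cropped by minimal enclosing rectangles) are
   summarised by 19 features (per-blob color means, histogram contrast,
   GLCM angular second moment, size w×h, aspect w/h) and classified
   multi-fruit / single-fruit / non-fruit by a random forest; non-fruit
   speckles are discarded.
3. **Individual fruit localization.** Single-fruit blobs yield their
   mask centroid. Multi-fruit blobs (trusses of touching fruits) are
   resolved via the flash highlights: the map V·(1−S) from the HSV
   value and inverted saturation channels is clustered with X-means
   (BIC-driven split acceptance), the brightest cluster is kept, and
   each connected highlight region becomes one detection.

Detections are scored against ground truth with stage-stratified

    recall    = matched fruits     / all fruits
    precision = matched detections / all detections

Since no public labeled imagery exists for this setting, the package
includes a seeded synthetic canopy-scene generator with exact per-pixel
ground truth (flash-lit nighttime scenes: shaded fruit disks with
specular highlights, tangent-fruit trusses, leaves with glints, stems
colored confusably close to young fruits, impulse + Gaussian sensor
noise, optional occlusion). All pipeline stages are trained and
evaluated on it.

## A worked example

```r
library(tomascan)

scfg <- scene_config()                       # the standard study conditions

# stage-1 training: 1,400 fruit + 1,000 pixels per other class
px <- generate_pixel_training_set(
  scfg, c(background = 1000, fruit = 1400, leaf = 1000, stem = 1000),
  seed = 11)
pc <- train_pixel_classifier(px, seed = 12)

# stage-2 training: blobs harvested from the pixel stage's own output
bl <- generate_blob_training_set(scfg, counts = c(30, 200, 2000),
                                 pixel_classifier = pc, seed = 13)
bc <- train_blob_classifier(bl$features, bl$features$blob_class, seed = 14)
tidy(bc)          # mean-decrease-Gini importances; blob size ranks first

# detect and evaluate on a fresh scene
sc   <- generate_scene(scfg, seed = 501)
dets <- detect_fruits(sc$image, pc, bc)
detection_report(dets, sc$fruits)
```

```
Fruit detection report
  stage      recall     n
  young        1.00     2
  immature     1.00     7
  mature       1.00     2
  all          1.00    11
  precision   1.00   (11 detections, 11 matched)
```

On this scene all 11 fruits (including the truss, separated through its
highlights) are found with no false positives; the blob stage collapsed
241 candidate components to 8 fruit blobs (`attr(dets, "n_candidates")`
and `attr(dets, "n_fruit_blobs")`), and `tidy(bc)` ranks blob size
first in the importance list. Across 20 held-out scenes the same
models reach overall recall and precision above 0.95 with a ≥95%
candidate-blob reduction; see the acceptance script below for the exact
numbers on your machine.

`autoplot(sc)` renders a scene with its ground truth;
`plot_detections(sc$image, dets, sc$fruits)` overlays detections;
`autoplot(bc)` draws the importance ranking.

## Command-line pipeline

A four-stage, one-config workflow (also available as plain functions):

```sh
Rscript inst/cli/tomascan.R run --out-dir myrun --seed 1
# or individually: synth | train | detect | evaluate [--config cfg.yaml]
```

Each stage writes a provenance record (config hash, seed, model
checksums); a rerun from the same config and seed is byte-identical.
Exit codes: 0 success, 1 usage error, 2 data error.

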