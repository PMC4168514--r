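blob_from_mask <- function(mask, img = NULL, row0 = 1, col0 = 1,
                           blob_class = NA_character_) {
  if (is.null(img)) img <- flat_image(nrow(mask), ncol(mask), c(150, 40, 40))
  tibble::tibble(
    blob_id = 1L, row0 = row0, col0 = col0,
    height = nrow(mask), width = ncol(mask), npix = sum(mask),
    mask = list(mask), patch = list(img), blob_class = blob_class
  )
}

test_that("single-fruit position is the mask center of gravity", {
  # symmetric disk: centroid at the disk center
  m <- matrix(FALSE, 21, 21)
  for (i in 1:21) for (j in 1:21) if ((i - 11)^2 + (j - 11)^2 <= 64) m[i, j] <- TRUE
  d <- locate_single(blob_from_mask(m, row0 = 10, col0 = 20))
  expect_equal(c(d$row, d$col), c(11 + 9, 11 + 19))
  expect_equal(d$source, "single_blob_centroid")

  # single pixel at (7, 3) in image coordinates
  m1 <- matrix(FALSE, 9, 5); m1[7, 3] <- TRUE
  d1 <- locate_single(blob_from_mask(m1))
  expect_equal(c(d1$row, d1$col), c(7, 3))

  # L-shaped mask {(1,1),(2,1),(2,2)} -> mean coordinates (5/3, 4/3)
  mL <- matrix(FALSE, 3, 3); mL[1, 1] <- TRUE; mL[2, 1] <- TRUE; mL[2, 2] <- TRUE
  dL <- locate_single(blob_from_mask(mL))
  expect_equal(c(dL$row, dL$col), c(5 / 3, 4 / 3))

  expect_error(locate_single(blob_from_mask(matrix(FALSE, 2, 2))), "empty")
})

test_that("a flat-color blob yields at most one detection", {
  m <- matrix(TRUE, 10, 10)
  d <- locate_multi(blob_from_mask(m))
  expect_lte(nrow(d), 1)
})

test_that("touching fruits are separated through their flash highlights", {
  # two tangent fruits, each with one highlight
  sc2 <- generate_scene(truss_scene_config(fruits_per_truss = c(2, 2)),
                        seed = 41)
  blobs <- extract_blobs(sc2$classmap, sc2$image)
  expect_equal(nrow(blobs), 1)
  d <- locate_multi(blobs[1, ])
  expect_equal(nrow(d), 2)
  for (i in 1:2) {
    dist <- sqrt((sc2$fruits$hl_row - d$row[i])^2 +
                   (sc2$fruits$hl_col - d$col[i])^2)
    expect_lte(min(dist), 2)
  }
  expect_true(all(d$source == "multi_blob_highlight"))

  # five-fruit truss -> five detections
  sc5 <- generate_scene(truss_scene_config(fruits_per_truss = c(5, 5)),
                        seed = 43)
  blobs5 <- extract_blobs(sc5$classmap, sc5$image)
  expect_equal(nrow(blobs5), 1)
  d5 <- locate_multi(blobs5[1, ])
  expect_equal(nrow(d5), 5)
})

test_that("detections stay inside the parent blob's bounding box", {
  for (s in 1:5) {
    sc <- generate_scene(truss_scene_config(), seed = 60 + s)
    blobs <- extract_blobs(sc$classmap, sc$image)
    d <- locate_multi(blobs[1, ])
    expect_true(all(d$row >= blobs$row0[1] &
                      d$row <= blobs$row0[1] + blobs$height[1] - 1))
    expect_true(all(d$col >= blobs$col0[1] &
                      d$col <= blobs$col0[1] + blobs$width[1] - 1))
  }
})

test_that("the full cascade finds isolated fruits and truss members", {
  models <- study_models()

  # all-background image -> nothing detected
  bg <- flat_image(60, 80, c(10, 10, 14))
  d0 <- detect_fruits(bg, models$pixel, models$blob)
  expect_equal(nrow(d0), 0)

  # one isolated mature fruit -> exactly one detection inside its disk
  cfg1 <- scene_config(width = 120, height = 100, n_young = 0,
                       n_immature = 0, n_mature = 1, n_trusses = 0,
                       n_leaves = 0, n_stems = 0, occlusion = 0)
  sc1 <- generate_scene(cfg1, seed = 71)
  d1 <- detect_fruits(sc1$image, models$pixel, models$blob)
  expect_equal(nrow(d1), 1)
  f <- sc1$fruits[1, ]
  expect_lte(sqrt((d1$row - f$row)^2 + (d1$col - f$col)^2), f$radius)

  # singles plus one truss under easy rendering: all fruits found
  cfg2 <- scene_config(n_young = 0, n_immature = 2, n_mature = 2,
                       n_trusses = 1, fruits_per_truss = c(3, 3),
                       occlusion = 0)
  sc2 <- generate_scene(cfg2, seed = 72)
  d2 <- detect_fruits(sc2$image, models$pixel, models$blob)
  expect_equal(nrow(d2), nrow(sc2$fruits))

  # detections are sorted row-major and reproducible
  expect_true(!is.unsorted(d2$row))
  d2b <- detect_fruits(sc2$image, models$pixel, models$blob)
  expect_identical(as.data.frame(d2), as.data.frame(d2b))

  # no detection originates from a non-fruit blob
  cm <- segment_pixels(models$pixel, sc2$image)
  blobs <- classify_blobs(models$blob, extract_blobs(cm, sc2$image))
  non_ids <- blobs$blob_id[blobs$blob_class == "non_fruit"]
  expect_false(any(d2$blob_id %in% non_ids))
})

test_that("detections serialize to CSV and GeoJSON points", {
  dets <- tibble::tibble(row = c(10.5, 20), col = c(3, 40.25),
                         source = c("single_blob_centroid",
                                    "multi_blob_highlight"),
                         blob_id = c(1L, 2L))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_detections(dets, tmp, image_id = "scene_007")
  back <- read.csv(tmp)
  expect_equal(back$row, dets$row)
  expect_equal(back$image_id, rep("scene_007", 2))

  gj <- jsonlite::fromJSON(detections_geojson(dets), simplifyVector = FALSE)
  expect_equal(gj$type, "FeatureCollection")
  expect_length(gj$features, 2)
  expect_equal(gj$features[[1]]$geometry$coordinates[[2]], 10.5)  # y = row
  expect_equal(gj$features[[2]]$properties$source, "multi_blob_highlight")
})
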