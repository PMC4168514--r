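make_classmap <- function(h, w, fruit_idx) {
  cm <- matrix(0L, h, w)
  cm[fruit_idx] <- 1L
  cm
}

test_that("blob extraction finds 8-connected components with minimal boxes", {
  img <- flat_image(12, 12, c(200, 40, 40))

  # no fruit pixels -> no blobs
  expect_equal(nrow(extract_blobs(matrix(0L, 12, 12), img)), 0)

  # diagonal-only touch is one blob under 8-connectivity
  cm <- matrix(0L, 12, 12); cm[3, 3] <- 1L; cm[4, 4] <- 1L
  blobs <- extract_blobs(cm, img)
  expect_equal(nrow(blobs), 1)
  expect_equal(blobs$npix, 2)
  expect_equal(c(blobs$row0, blobs$col0, blobs$height, blobs$width),
               c(3, 3, 2, 2))

  # a disk plus an isolated pixel -> two blobs, boxes match a flood fill
  cm2 <- matrix(0L, 30, 30)
  for (i in 1:30) for (j in 1:30) {
    if ((i - 12)^2 + (j - 12)^2 <= 5^2) cm2[i, j] <- 1L
  }
  cm2[25, 25] <- 1L
  img2 <- flat_image(30, 30, c(200, 40, 40))
  blobs2 <- extract_blobs(cm2, img2)
  expect_equal(nrow(blobs2), 2)
  lab <- oracle_label8(cm2 == 1L)
  expect_equal(max(lab), 2)
  # mask touches all four bbox edges
  for (b in seq_len(2)) {
    m <- blobs2$mask[[b]]
    expect_true(any(m[1, ]) && any(m[nrow(m), ]) &&
                  any(m[, 1]) && any(m[, ncol(m)]))
  }
  expect_error(extract_blobs(matrix(0L, 5, 5), img), "dimensions")
})

test_that("blob masks partition the fruit-pixel set exactly", {
  set.seed(21)
  cm <- matrix(as.integer(runif(40 * 40) < 0.2), 40, 40)
  img <- flat_image(40, 40, c(150, 60, 60))
  blobs <- extract_blobs(cm, img)
  cover <- matrix(0L, 40, 40)
  for (b in seq_len(nrow(blobs))) {
    m <- blobs$mask[[b]]
    sub <- cover[blobs$row0[b] + seq_len(nrow(m)) - 1,
                 blobs$col0[b] + seq_len(ncol(m)) - 1]
    cover[blobs$row0[b] + seq_len(nrow(m)) - 1,
          blobs$col0[b] + seq_len(ncol(m)) - 1] <- sub + m
  }
  expect_true(all(cover[cm == 1L] == 1L))   # covered exactly once
  expect_true(all(cover[cm == 0L] == 0L))   # nothing invented
  # and labeling agrees with the brute-force flood fill
  expect_equal(nrow(blobs), max(oracle_label8(cm == 1L)))
})

test_that("grayscale is BT.601 luma rounded to integers", {
  expect_equal(as.numeric(grayscale(flat_image(1, 1, c(255, 255, 255)))), 255)
  expect_equal(as.numeric(grayscale(flat_image(1, 1, c(0, 0, 0)))), 0)
  expect_equal(as.numeric(grayscale(flat_image(1, 1, c(255, 0, 0)))),
               round(0.299 * 255))
  img <- flat_image(3, 2, c(37, 201, 96))
  expect_true(all(grayscale(img) ==
                    round(0.299 * 37 + 0.587 * 201 + 0.114 * 96)))
})

test_that("GLCM angular second moment matches enumeration and the oracle", {
  expect_equal(glcm_asm(matrix(7L, 5, 5)), 1)

  # 2x2 checkerboard {0,1}: symmetric pairs p(0,1) = p(1,0) = 0.5
  checker <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  expect_equal(glcm_asm(checker), 0.5)

  set.seed(9)
  for (rep in 1:100) {
    g <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
    expect_equal(glcm_asm(g), oracle_glcm_asm(g), tolerance = 1e-12)
  }
  expect_error(glcm_asm(matrix(1L, 3, 1)),
               class = "tomascan_undefined_texture")
})

test_that("histogram contrast is the second central moment", {
  expect_equal(hist_contrast(matrix(42L, 4, 4)), 0)
  two_level <- matrix(c(0L, 255L), 2, 4)
  expect_equal(hist_contrast(two_level), 127.5^2)
  set.seed(10)
  g <- matrix(sample(0:255, 48, replace = TRUE), 6, 8)
  v <- as.numeric(g)
  expect_equal(hist_contrast(g), mean((v - mean(v))^2))
  m <- matrix(FALSE, 6, 8)
  expect_error(hist_contrast(g, m), "Empty mask")
})

test_that("blob feature vectors have the documented 19 components", {
  # 10 x 5 bbox: size 50, aspect 0.5 height/width orientation fixed below
  cm <- matrix(0L, 20, 20)
  cm[6:15, 3:7] <- 1L     # height 10, width 5
  img <- flat_image(20, 20, c(200, 40, 40))
  blobs <- extract_blobs(cm, img)
  f <- blob_features(blobs)
  expect_named(f, c("blob_id", blob_feature_names()))
  expect_equal(f$size, 50)
  expect_equal(f$aspect, 5 / 10)

  # single-pixel blob: degenerate texture limits
  cm1 <- matrix(0L, 5, 5); cm1[3, 3] <- 1L
  f1 <- blob_features(extract_blobs(cm1, flat_image(5, 5, c(9, 9, 9))))
  expect_equal(f1$size, 1)
  expect_equal(f1$aspect, 1)
  expect_equal(f1$glcm_asm, 1)
  expect_equal(f1$hist_contrast, 0)

  # uniform color: blob color means equal the pixel's feature vector
  expect_equal(as.numeric(f[1, color_feature_names()]),
               as.numeric(pixel_features(c(200, 40, 40))[1, ]),
               tolerance = 1e-9)
})

make_size_blobset <- function(seed = 1) {
  # classes differ only by size: same color, same texture
  set.seed(seed)
  sizes <- list(multi_fruit = 28:35, single_fruit = 10:16, non_fruit = 1:3)
  purrr::map_dfr(names(sizes), function(cls) {
    purrr::map_dfr(1:40, function(i) {
      side <- sample(sizes[[cls]], 1)
      cm <- matrix(0L, side + 4, side + 4)
      cm[3:(side + 2), 3:(side + 2)] <- 1L
      img <- flat_image(side + 4, side + 4, c(150, 60, 60)) +
        array(rnorm((side + 4)^2 * 3, 0, 2), dim = c(side + 4, side + 4, 3))
      img <- pmin(pmax(round(img), 0), 255)
      f <- blob_features(extract_blobs(cm, img))
      f$blob_class <- cls
      f
    })
  })
}

test_that("size dominates importance when classes differ only by size", {
  train <- make_size_blobset(seed = 31)
  clf <- train_blob_classifier(train, train$blob_class, ntree = 200, seed = 5)
  imp <- tidy(clf)
  expect_true(all(imp$mean_decrease_gini >= 0))
  expect_equal(imp$feature[1], "size")
  # reproducible at fixed seed
  clf2 <- train_blob_classifier(train, train$blob_class, ntree = 200, seed = 5)
  expect_identical(tidy(clf2), imp)
  # near-zero out-of-bag error on separable classes
  expect_lte(glance(clf)$oob_error, 0.05)
})

test_that("label permutation destroys out-of-bag accuracy", {
  train <- make_size_blobset(seed = 32)
  set.seed(8)
  perm <- sample(train$blob_class)
  clf <- train_blob_classifier(train, perm, ntree = 200, seed = 5)
  # accuracy should be near the class prior (1/3 here), far from separable
  expect_lte(1 - glance(clf)$oob_error, 0.5)
})

test_that("missing blob class aborts training", {
  train <- make_size_blobset()
  sub <- train[train$blob_class != "multi_fruit", ]
  expect_error(train_blob_classifier(sub, sub$blob_class),
               class = "tomascan_degenerate_training")
})

test_that("speckle blobs are filtered and filtering only removes blobs", {
  models <- study_models()
  sc <- generate_scene(models$scene_config, seed = 881)
  cm <- segment_pixels(models$pixel, sc$image)
  blobs <- extract_blobs(cm, sc$image)
  classified <- classify_blobs(models$blob, blobs)
  expect_true(all(classified$blob_class %in% blob_class_levels()))

  # few-pixel speckles overwhelmingly rejected as non-fruit
  speck <- classified$blob_class[classified$npix <= 3]
  expect_gte(mean(speck == "non_fruit"), 0.95)

  # filtering is a pure subset: candidates only ever shrink
  kept <- classified[classified$blob_class != "non_fruit", ]
  expect_lte(nrow(kept), nrow(blobs))
  expect_true(all(kept$blob_id %in% blobs$blob_id))

  # the candidate count collapses to near the true fruit-region count
  expect_gte(nrow(blobs), 10 * nrow(kept))
})
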