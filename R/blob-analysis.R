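#' 8-connected component labeling
#'
#' Labels connected regions of a logical/binary matrix under
#' 8-connectivity (diagonal neighbors touch, matching the 8-neighbor
#' pixel notion used when collecting training pixels). Built on
#' `EBImage::bwlabel()` (4-connected) followed by a union-find merge of
#' labels that touch diagonally.
#'
#' @param mask A logical or 0/1 matrix.
#' @return An integer matrix; background 0, components numbered from 1.
#' @export
label_components <- function(mask) {
  if (!is.matrix(mask)) abort("`mask` must be a matrix.")
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab <- EBImage::imageData(EBImage::bwlabel(m))
  storage.mode(lab) <- "integer"
  nlab <- max(lab)
  if (nlab <= 1) return(lab)

  # merge labels adjacent along the two diagonal directions
  h <- nrow(lab); w <- ncol(lab)
  a1 <- lab[-h, -w]; b1 <- lab[-1, -1]   # down-right
  a2 <- lab[-h, -1]; b2 <- lab[-1, -w]   # down-left
  pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  parent <- seq_len(nlab)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pairs) > 0) {
    pairs <- unique(pairs)
    for (k in seq_len(nrow(pairs))) {
      ri <- find(pairs[k, 1]); rj <- find(pairs[k, 2])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(nlab), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Extract candidate blobs from the fruit class
#'
#' Each 8-connected component of fruit pixels becomes one blob: its
#' minimal enclosing rectangle (the mask touches all four edges), the
#' binary membership mask, and the RGB crop of the rectangle. Blobs are
#' ordered row-major by rectangle origin. Masks are pairwise disjoint and
#' jointly cover the fruit-pixel set exactly.
#'
#' @param classmap Integer class-map matrix (code 1 = fruit).
#' @param image The matching H x W x 3 RGB array in \[0, 255\].
#' @return A tibble with one row per blob: `blob_id`, bounding box
#'   (`row0`, `col0`, `height`, `width`, 1-based image coordinates),
#'   pixel count `npix`, list-columns `mask` (logical matrix) and `patch`
#'   (RGB array), and `blob_class` (`NA` until [classify_blobs()]).
#' @export
extract_blobs <- function(classmap, image) {
  check_classmap(classmap)
  check_rgb_image(image)
  if (!all(dim(classmap) == dim(image)[1:2])) {
    abort("`classmap` and `image` dimensions differ.")
  }
  lab <- label_components(classmap == 1L)
  nlab <- max(lab)
  if (nlab == 0) return(empty_blob_tbl())

  idx <- which(lab > 0, arr.ind = TRUE)
  ids <- lab[lab > 0]
  rows_by <- split(idx[, 1], ids)
  cols_by <- split(idx[, 2], ids)
  blobs <- purrr::map_dfr(seq_len(nlab), function(i) {
    rr <- rows_by[[i]]; cc <- cols_by[[i]]
    r0 <- min(rr); r1 <- max(rr); c0 <- min(cc); c1 <- max(cc)
    m <- matrix(FALSE, r1 - r0 + 1, c1 - c0 + 1)
    m[cbind(rr - r0 + 1, cc - c0 + 1)] <- TRUE
    tibble(
      blob_id = i,
      row0 = r0, col0 = c0,
      height = r1 - r0 + 1L, width = c1 - c0 + 1L,
      npix = length(rr),
      mask = list(m),
      patch = list(image[r0:r1, c0:c1, , drop = FALSE]),
      blob_class = NA_character_
    )
  })
  blobs <- dplyr::arrange(blobs, .data$row0, .data$col0)
  blobs$blob_id <- seq_len(nrow(blobs))
  blobs
}

empty_blob_tbl <- function() {
  tibble(
    blob_id = integer(), row0 = integer(), col0 = integer(),
    height = integer(), width = integer(), npix = integer(),
    mask = list(), patch = list(), blob_class = character()
  )
}

#' BT.601 grayscale conversion
#'
#' Luma `0.299 R + 0.587 G + 0.114 B`, rounded to the nearest integer.
#'
#' @param patch An H x W x 3 RGB array in \[0, 255\].
#' @return An integer H x W matrix in \[0, 255\].
#' @export
grayscale <- function(patch) {
  check_rgb_image(patch)
  d <- dim(patch)
  flat <- matrix(patch, ncol = 3)
  g <- matrix(round(0.299 * flat[, 1] + 0.587 * flat[, 2] + 0.114 * flat[, 3]),
              nrow = d[1], ncol = d[2])
  storage.mode(g) <- "integer"
  g
}

#' Angular second moment of the gray-level co-occurrence matrix
#'
#' The GLCM is built over 256 gray levels with the single offset (0, 1)
#' (horizontal neighbor) made symmetric, normalized to sum to one; the
#' ASM is the sum of squared entries. It equals 1 exactly when all
#' evaluated pixel pairs share one gray value (constant texture) and
#' approaches 0 for busy texture. By default the full rectangular patch
#' is evaluated, matching how blobs are cropped before texture analysis;
#' pass `mask` to restrict pairs to pixels where both members are inside
#' the mask.
#'
#' @param gray An integer matrix of gray levels in \[0, 255\].
#' @param mask Optional logical matrix of the same size.
#' @return A number in (0, 1\].
#' @export
glcm_asm <- function(gray, mask = NULL) {
  if (!is.matrix(gray)) abort("`gray` must be a matrix.")
  if (ncol(gray) < 2) {
    abort("Too few pixel pairs for a GLCM at offset (0, 1).",
          class = "tomascan_undefined_texture")
  }
  a <- gray[, -ncol(gray), drop = FALSE]
  b <- gray[, -1, drop = FALSE]
  if (!is.null(mask)) {
    ok <- mask[, -ncol(mask), drop = FALSE] & mask[, -1, drop = FALSE]
    a <- a[ok]; b <- b[ok]
  }
  if (length(a) == 0) {
    abort("Too few pixel pairs for a GLCM at offset (0, 1).",
          class = "tomascan_undefined_texture")
  }
  # symmetric pairs: count (a,b) and (b,a); ASM from normalized counts
  key <- c(a * 256 + b, b * 256 + a)
  counts <- table(key)
  p <- as.numeric(counts) / length(key)
  sum(p^2)
}

#' First-order histogram contrast
#'
#' The variance (second central moment) of the gray-level distribution —
#' the conventional first-order "contrast" statistic. 0 for a constant
#' patch.
#'
#' @inheritParams glcm_asm
#' @return A non-negative number.
#' @export
hist_contrast <- function(gray, mask = NULL) {
  if (!is.matrix(gray)) abort("`gray` must be a matrix.")
  v <- if (is.null(mask)) as.numeric(gray) else as.numeric(gray[mask])
  if (length(v) == 0) abort("Empty mask: histogram contrast is undefined.")
  mean((v - mean(v))^2)
}

#' The 19 blob features
#'
#' For each blob: the mean of each of the 15 color features over the
#' blob's member (mask) pixels; the histogram contrast and GLCM angular
#' second moment of the grayscale rectangle crop; the blob size
#' (`width * height`) and aspect ratio (`width / height`). Blobs whose
#' patch supports no GLCM pair (single-column crops) take the
#' constant-texture limits ASM = 1, contrast as computed on the pixels
#' present.
#'
#' @param blobs A blob tibble from [extract_blobs()].
#' @param color_on_mask Average color features over mask pixels only
#'   (default) or over the full rectangle.
#' @return A tibble: `blob_id` plus the 19 columns of
#'   [blob_feature_names()].
#' @export
blob_features <- function(blobs, color_on_mask = TRUE) {
  if (nrow(blobs) == 0) {
    out <- as_tibble(matrix(numeric(), 0, 20,
      dimnames = list(NULL, c("blob_id", blob_feature_names()))))
    return(out)
  }
  purrr::pmap_dfr(
    blobs[c("blob_id", "width", "height", "mask", "patch")],
    function(blob_id, width, height, mask, patch) {
      rgbflat <- matrix(patch, ncol = 3)
      keep <- if (color_on_mask) as.vector(mask) else rep(TRUE, nrow(rgbflat))
      cf <- colMeans(color_feature_matrix(rgbflat[keep, , drop = FALSE]))
      gray <- grayscale(patch)
      asm <- tryCatch(glcm_asm(gray),
                      tomascan_undefined_texture = function(e) 1)
      hc <- hist_contrast(gray)
      tibble(
        blob_id = blob_id,
        !!!as.list(cf),
        hist_contrast = hc,
        glcm_asm = asm,
        size = as.numeric(width) * height,
        aspect = width / height
      )
    }
  )
}

#' Train the random-forest blob classifier
#'
#' Fits a random forest separating multi-fruit, single-fruit and
#' non-fruit blobs from the 19 blob features. Defaults follow the
#' classical formulation: 500 trees, floor(sqrt(19)) = 4 candidate
#' features per split, bootstrap sampling. Mean-decrease-Gini feature
#' importances are exposed via `tidy()`.
#'
#' @param features A data frame containing the 19 feature columns
#'   ([blob_feature_names()]).
#' @param labels Character vector of blob classes
#'   ([blob_class_levels()]); all three classes must be present.
#' @param ntree,mtry Forest size and features tried per split.
#' @param seed Integer RNG seed; refitting with the same seed reproduces
#'   the forest exactly.
#' @return A `blob_classifier` object.
#' @export
train_blob_classifier <- function(features, labels, ntree = 500,
                                  mtry = floor(sqrt(19)), seed = 1L) {
  features <- as_tibble(features)
  missing <- setdiff(blob_feature_names(), names(features))
  if (length(missing) > 0) {
    abort(paste0("`features` is missing columns: ", paste(missing, collapse = ", ")))
  }
  if (!all(labels %in% BLOB_CLASS_LEVELS)) {
    abort(paste0("Labels must be one of: ", paste(BLOB_CLASS_LEVELS, collapse = ", ")))
  }
  if (!all(BLOB_CLASS_LEVELS %in% labels)) {
    abort("All three blob classes must be present in the training labels.",
          class = "tomascan_degenerate_training")
  }
  x <- as.data.frame(features[blob_feature_names()])
  y <- factor(labels, levels = BLOB_CLASS_LEVELS)
  set.seed(seed)
  fit <- randomForest::randomForest(x = x, y = y, ntree = ntree, mtry = mtry)
  structure(
    list(
      fit = fit,
      class_counts = table(y),
      hyperparams = list(ntree = ntree, mtry = mtry),
      seed = seed
    ),
    class = "blob_classifier"
  )
}

#' @export
print.blob_classifier <- function(x, ...) {
  cat("<blob_classifier: random forest over 19 blob features>\n")
  cat("  training blobs:",
      paste(sprintf("%s=%d", names(x$class_counts), x$class_counts),
            collapse = ", "), "\n")
  cat(sprintf("  trees: %d, mtry: %d, OOB error: %.3f\n",
              x$hyperparams$ntree, x$hyperparams$mtry,
              mean(x$fit$err.rate[x$hyperparams$ntree, "OOB"])))
  invisible(x)
}

#' @describeIn train_blob_classifier `tidy()` returns feature importances
#'   (mean decrease Gini), sorted descending.
#' @param x,object A `blob_classifier`.
#' @param ... Unused.
#' @method tidy blob_classifier
#' @export
tidy.blob_classifier <- function(x, ...) {
  imp <- randomForest::importance(x$fit, type = 2)
  tbl <- tibble(feature = rownames(imp), mean_decrease_gini = imp[, 1])
  dplyr::arrange(tbl, desc(.data$mean_decrease_gini))
}

#' @describeIn train_blob_classifier `glance()` returns a one-row tibble
#'   with training size and out-of-bag error.
#' @method glance blob_classifier
#' @export
glance.blob_classifier <- function(x, ...) {
  tibble(
    n = sum(x$class_counts),
    ntree = x$hyperparams$ntree,
    mtry = x$hyperparams$mtry,
    oob_error = as.numeric(x$fit$err.rate[x$hyperparams$ntree, "OOB"])
  )
}

#' Classify candidate blobs
#'
#' Assigns each blob one of the three blob classes; downstream stages
#' drop `non_fruit` blobs, which is where the pixel stage's false
#' positives are eliminated.
#'
#' @param classifier A `blob_classifier`.
#' @param blobs A blob tibble from [extract_blobs()].
#' @param features Optional precomputed [blob_features()] for `blobs`.
#' @return `blobs` with `blob_class` filled in.
#' @export
classify_blobs <- function(classifier, blobs, features = NULL) {
  if (!inherits(classifier, "blob_classifier")) {
    abort("`classifier` must be a fitted blob_classifier.")
  }
  if (nrow(blobs) == 0) return(blobs)
  if (is.null(features)) features <- blob_features(blobs)
  x <- as.data.frame(features[blob_feature_names()])
  blobs$blob_class <- as.character(predict(classifier$fit, newdata = x))
  blobs
}

#' @describeIn train_blob_classifier `autoplot()` draws the
#'   mean-decrease-Gini importance ranking.
#' @method autoplot blob_classifier
#' @export
autoplot.blob_classifier <- function(object, ...) {
  imp <- tidy(object)
  ggplot2::ggplot(imp, ggplot2::aes(
    x = .data$mean_decrease_gini,
    y = stats::reorder(.data$feature, .data$mean_decrease_gini)
  )) +
    ggplot2::geom_col(fill = "#b2182b") +
    ggplot2::labs(x = "Mean decrease Gini", y = NULL,
                  title = "Blob-feature importance") +
    ggplot2::theme_minimal()
}
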