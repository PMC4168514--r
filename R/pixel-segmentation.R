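#' Collect labeled training pixels around seed points
#'
#' Re-creates the click-to-label workflow used to build the pixel
#' training set: for every seed point the seed pixel and its 8 neighbors
#' (clipped at image borders) are extracted with the seed's label, so an
#' interior seed contributes 9 samples. Duplicates from adjacent seeds
#' are kept.
#'
#' @param image An H x W x 3 array in \[0, 255\].
#' @param seeds A data frame with columns `row`, `col` (1-based pixel
#'   coordinates) and `label` (one of [class_levels()]).
#' @return A tibble with `row`, `col`, `label` and the 15 color-feature
#'   columns, one row per collected pixel.
#' @export
collect_training_pixels <- function(image, seeds) {
  check_rgb_image(image)
  seeds <- as_tibble(seeds)
  if (!all(c("row", "col", "label") %in% names(seeds))) {
    abort("`seeds` needs columns row, col, label.")
  }
  d <- dim(image)
  if (any(seeds$row < 1 | seeds$row > d[1] | seeds$col < 1 | seeds$col > d[2])) {
    abort("Seed coordinates fall outside the image.")
  }
  if (!all(seeds$label %in% CLASS_LEVELS)) {
    abort(paste0("Labels must be one of: ", paste(CLASS_LEVELS, collapse = ", ")))
  }
  off <- expand.grid(dr = -1:1, dc = -1:1)
  pts <- purrr::pmap_dfr(seeds, function(row, col, label) {
    rr <- row + off$dr
    cc <- col + off$dc
    keep <- rr >= 1 & rr <= d[1] & cc >= 1 & cc <= d[2]
    tibble(row = rr[keep], col = cc[keep], label = label)
  })
  rgb <- cbind(
    image[cbind(pts$row, pts$col, 1)],
    image[cbind(pts$row, pts$col, 2)],
    image[cbind(pts$row, pts$col, 3)]
  )
  dplyr::bind_cols(pts, pixel_features(rgb))
}

#' Collect labeled training pixels from a full label mask
#'
#' Batch alternative to [collect_training_pixels()]: every labeled pixel
#' of an indexed class-map mask (or an optional per-class subsample of
#' them) becomes one training sample.
#'
#' @inheritParams collect_training_pixels
#' @param mask Integer matrix of class codes 0..3 (see [read_classmap()]).
#' @param n_per_class Optional cap: sample at most this many pixels per
#'   class (scalar or named by [class_levels()]).
#' @param seed RNG seed for the subsample.
#' @return A tibble with `row`, `col`, `label` and the 15 feature
#'   columns.
#' @export
pixel_samples_from_mask <- function(image, mask, n_per_class = NULL,
                                    seed = 1L) {
  check_rgb_image(image)
  check_classmap(mask)
  if (!all(dim(mask) == dim(image)[1:2])) {
    abort("`mask` and `image` dimensions differ.")
  }
  if (!is.null(n_per_class) && length(n_per_class) == 1) {
    n_per_class <- stats::setNames(rep(n_per_class, 4), CLASS_LEVELS)
  }
  set.seed(seed)
  out <- lapply(0:3, function(code) {
    idx <- which(mask == code)
    if (length(idx) == 0) return(NULL)
    cls <- CLASS_LEVELS[code + 1]
    if (!is.null(n_per_class)) {
      idx <- sample(idx, min(n_per_class[[cls]], length(idx)))
    }
    rr <- (idx - 1) %% nrow(mask) + 1
    cc <- (idx - 1) %/% nrow(mask) + 1
    rgb <- cbind(image[cbind(rr, cc, 1)], image[cbind(rr, cc, 2)],
                 image[cbind(rr, cc, 3)])
    dplyr::bind_cols(tibble(row = rr, col = cc, label = cls),
                     pixel_features(rgb))
  })
  bind_rows(out)
}

#' Train the CART pixel classifier
#'
#' Fits a classification tree (CART, Gini impurity) mapping the 15 color
#' features to the four pixel classes. Defaults: no complexity pruning
#' (`cp = 0`), minimum 50 samples per leaf, no cross-validation, no class
#' reweighting; all are exposed. Training is deterministic given the seed.
#'
#' @param samples A data frame holding the 15 feature columns plus a
#'   `label` column, e.g. from [collect_training_pixels()] or
#'   [generate_pixel_training_set()].
#' @param minbucket Minimum samples per leaf.
#' @param cp rpart complexity parameter (0 disables cost-complexity
#'   pruning).
#' @param maxdepth Maximum tree depth.
#' @param class_weights Optional named numeric vector of per-class prior
#'   weights; `NULL` keeps the empirical priors (no reweighting).
#' @param seed Integer RNG seed recorded with the model.
#' @return A `pixel_classifier` object.
#' @export
train_pixel_classifier <- function(samples, minbucket = 50, cp = 0,
                                   maxdepth = 30, class_weights = NULL,
                                   seed = 1L) {
  samples <- as_tibble(samples)
  missing <- setdiff(c(COLOR_FEATURE_NAMES, "label"), names(samples))
  if (length(missing) > 0) {
    abort(paste0("`samples` is missing columns: ", paste(missing, collapse = ", ")))
  }
  feats <- as.matrix(samples[COLOR_FEATURE_NAMES])
  if (any(!is.finite(feats))) abort("All features must be finite.")
  present <- intersect(CLASS_LEVELS, unique(samples$label))
  if (length(present) < 2) {
    abort("Need at least two classes to train the pixel classifier.",
          class = "tomascan_degenerate_training")
  }
  df <- as.data.frame(samples[COLOR_FEATURE_NAMES])
  df$label <- factor(samples$label, levels = present)

  parms <- list(split = "gini")
  if (!is.null(class_weights)) {
    w <- class_weights[present]
    parms$prior <- w / sum(w)
  }
  set.seed(seed)
  fit <- rpart::rpart(
    label ~ ., data = df, method = "class", parms = parms,
    control = rpart::rpart.control(
      minsplit = 2 * minbucket, minbucket = minbucket, cp = cp,
      maxdepth = maxdepth, xval = 0
    )
  )
  structure(
    list(
      fit = fit,
      classes = present,
      class_counts = table(samples$label)[present],
      hyperparams = list(minbucket = minbucket, cp = cp, maxdepth = maxdepth,
                         class_weights = class_weights),
      seed = seed
    ),
    class = "pixel_classifier"
  )
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat("<pixel_classifier: CART over 15 color features>\n")
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  cat("  training pixels:",
      paste(sprintf("%s=%d", names(x$class_counts), x$class_counts),
            collapse = ", "), "\n")
  cat("  leaves:", sum(x$fit$frame$var == "<leaf>"), "\n")
  invisible(x)
}

#' @describeIn train_pixel_classifier `tidy()` returns one row per tree
#'   split: the split feature, threshold, and number of training samples
#'   reaching the node, in frame order (root first).
#' @param x,object A `pixel_classifier`.
#' @param ... Unused.
#' @method tidy pixel_classifier
#' @export
tidy.pixel_classifier <- function(x, ...) {
  fr <- x$fit$frame
  splits_idx <- which(fr$var != "<leaf>")
  if (length(splits_idx) == 0) {
    return(tibble(feature = character(), threshold = double(), n = integer()))
  }
  # primary split rows in x$fit$splits come in frame order, count per node
  sp <- x$fit$splits
  ncompete <- fr$ncompete + fr$nsurrogate + 1L
  first_row <- cumsum(c(1L, ncompete[fr$var != "<leaf>"]))
  first_row <- first_row[seq_along(splits_idx)]
  tibble(
    feature = as.character(fr$var[splits_idx]),
    threshold = sp[first_row, "index"],
    n = fr$n[splits_idx]
  )
}

#' @describeIn train_pixel_classifier `glance()` returns a one-row tibble
#'   with sample counts, class count, number of leaves and training
#'   accuracy.
#' @method glance pixel_classifier
#' @export
glance.pixel_classifier <- function(x, ...) {
  pred <- predict(x$fit, type = "class")
  actual <- x$fit$model$label %||% attr(x$fit, "ylevels")[x$fit$y]
  actual <- x$classes[x$fit$y]
  tibble(
    n = sum(x$class_counts),
    n_classes = length(x$classes),
    n_leaves = sum(x$fit$frame$var == "<leaf>"),
    train_accuracy = mean(as.character(pred) == actual)
  )
}

#' Segment an image into the four pixel classes
#'
#' Applies a fitted [train_pixel_classifier()] tree to every pixel,
#' producing a class map (integer matrix of codes 0 background, 1 fruit,
#' 2 leaf, 3 stem). Prediction is pure: the same model and image always
#' give the same map.
#'
#' @param classifier A `pixel_classifier`.
#' @param image An H x W x 3 array in \[0, 255\].
#' @return An integer matrix the size of the image.
#' @export
segment_pixels <- function(classifier, image) {
  if (!inherits(classifier, "pixel_classifier")) {
    abort("`classifier` must be a fitted pixel_classifier.")
  }
  check_rgb_image(image)
  d <- dim(image)
  feats <- as.data.frame(color_feature_matrix(matrix(image, ncol = 3)))
  pred <- as.character(predict(classifier$fit, newdata = feats, type = "class"))
  codes <- match(pred, CLASS_LEVELS) - 1L
  matrix(codes, nrow = d[1], ncol = d[2])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
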