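#' Per-pixel color features across five color spaces
#'
#' Computes the 15 color features used by the pixel classifier:
#' normalized chromaticity `r, g, b`; HSV `H, S, V`; CIELAB
#' `Lstar, astar, bstar`; CIELUV `Lstar_uv, ustar, vstar`; and BT.601
#' full-range `Y, Cb, Cr`.
#'
#' Conventions (the method itself fixes none, so they are pinned here):
#' sRGB primaries with D65 white point for CIELAB/CIELUV; BT.601
#' full-range for YCbCr (`Y`, `Cb`, `Cr` in \[0, 255\]); hue in degrees
#' \[0, 360), defined as 0 for achromatic pixels; normalized chromaticity
#' defined as `r = g = b = 1/3` at black (R+G+B = 0) so the sum-to-one
#' invariant holds everywhere. All arithmetic is in double precision with
#' no intermediate 8-bit re-quantization.
#'
#' @param rgb An n x 3 numeric matrix of 8-bit RGB values in \[0, 255\]
#'   (a length-3 vector is treated as a single pixel).
#' @return A tibble with n rows and the 15 feature columns in the order
#'   given by [color_feature_names()].
#' @examples
#' pixel_features(c(255, 0, 0))       # pure red: H = 0, S = V = 1
#' pixel_features(rbind(c(0, 0, 0), c(255, 255, 255)))
#' @export
pixel_features <- function(rgb) {
  as_tibble(color_feature_matrix(rgb))
}

# n x 15 numeric matrix; fast path shared by pixel_features()/feature_planes()
color_feature_matrix <- function(rgb) {
  if (is.null(dim(rgb))) rgb <- matrix(rgb, ncol = 3)
  rgb <- as.matrix(rgb)
  if (ncol(rgb) != 3) abort("`rgb` must have 3 columns (R, G, B).")
  if (any(rgb < 0 | rgb > 255) || anyNA(rgb)) {
    abort("RGB values must be finite and in [0, 255].")
  }
  R <- rgb[, 1]; G <- rgb[, 2]; B <- rgb[, 3]

  # normalized chromaticity; black pixels are achromatic -> 1/3 each
  tot <- R + G + B
  zero <- tot == 0
  tot[zero] <- 3
  r <- ifelse(zero, 1, R) / tot
  g <- ifelse(zero, 1, G) / tot
  b <- ifelse(zero, 1, B) / tot

  hsv <- grDevices::rgb2hsv(t(rgb), maxColorValue = 255)
  H <- hsv[1, ] * 360
  H[H >= 360] <- 0
  S <- hsv[2, ]
  V <- hsv[3, ]
  H[S == 0] <- 0

  srgb <- rgb / 255
  lab <- grDevices::convertColor(srgb, from = "sRGB", to = "Lab")
  luv <- grDevices::convertColor(srgb, from = "sRGB", to = "Luv")

  # BT.601 full-range luma/chroma, kept on the [0, 255] scale
  Y  <-  0.299    * R + 0.587    * G + 0.114    * B
  Cb <- -0.168736 * R - 0.331264 * G + 0.5      * B + 128
  Cr <-  0.5      * R - 0.418688 * G - 0.081312 * B + 128

  out <- cbind(
    r, g, b, H, S, V,
    lab[, 1], lab[, 2], lab[, 3],
    luv[, 1], luv[, 2], luv[, 3],
    Y, Cb, Cr
  )
  colnames(out) <- COLOR_FEATURE_NAMES
  rownames(out) <- NULL
  out
}

#' Color-feature planes of a whole image
#'
#' Vectorized form of [pixel_features()]: one plane per feature, each the
#' size of the input image.
#'
#' @param image An H x W x 3 numeric array of 8-bit RGB values in
#'   \[0, 255\].
#' @return A named list of 15 H x W matrices, in [color_feature_names()]
#'   order.
#' @export
feature_planes <- function(image) {
  check_rgb_image(image)
  d <- dim(image)
  flat <- matrix(image, ncol = 3)        # column-major; pixel (i,j) -> row i + (j-1)*H
  feats <- color_feature_matrix(flat)
  planes <- lapply(seq_len(ncol(feats)), function(k) {
    matrix(feats[, k], nrow = d[1], ncol = d[2])
  })
  names(planes) <- COLOR_FEATURE_NAMES
  planes
}

#' Specular-highlight map
#'
#' The HSV value channel multiplied by the inverted saturation channel,
#' `V * (1 - S)`. Flash-overexposed regions (low saturation, high value)
#' score near 1, giving the cue used to separate touching fruits inside a
#' multi-fruit blob.
#'
#' @inheritParams feature_planes
#' @return An H x W matrix with values in \[0, 1\].
#' @export
highlight_map <- function(image) {
  check_rgb_image(image)
  d <- dim(image)
  hsv <- grDevices::rgb2hsv(t(matrix(image, ncol = 3)), maxColorValue = 255)
  matrix(hsv[3, ] * (1 - hsv[2, ]), nrow = d[1], ncol = d[2])
}

check_rgb_image <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3 || dim(image)[3] != 3) {
    abort("`image` must be an H x W x 3 array.")
  }
  if (dim(image)[1] < 1 || dim(image)[2] < 1) {
    abort("`image` must be non-empty.")
  }
  invisible(image)
}
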