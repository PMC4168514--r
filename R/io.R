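#' Read and write 8-bit RGB images
#'
#' PNG and TIFF are supported. Images are represented in R as
#' H x W x 3 numeric arrays with values in \[0, 255\] and channel order
#' RGB. Grayscale and RGBA files are normalized to three channels
#' (alpha is dropped).
#'
#' @param path File path; format is chosen by extension
#'   (`.png`, `.tif`, `.tiff`).
#' @return `read_rgb()` returns an H x W x 3 array in \[0, 255\];
#'   `write_rgb()` returns `path` invisibly.
#' @export
read_rgb <- function(path) {
  if (!file.exists(path)) abort(paste0("No such image file: ", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort(paste0("Unsupported image extension: .", ext))
  )
  if (is.matrix(img)) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  round(img * 255)
}

#' @rdname read_rgb
#' @param image An H x W x 3 array in \[0, 255\].
#' @export
write_rgb <- function(image, path) {
  check_rgb_image(image)
  ext <- tolower(tools::file_ext(path))
  scaled <- pmin(pmax(image / 255, 0), 1)
  switch(ext,
    png = png::writePNG(scaled, target = path),
    tif = ,
    tiff = tiff::writeTIFF(scaled, where = path),
    abort(paste0("Unsupported image extension: .", ext))
  )
  invisible(path)
}

#' Read and write class maps
#'
#' A class map is an integer matrix of per-pixel codes
#' (0 background, 1 fruit, 2 leaf, 3 stem; see [class_levels()]).
#' It is serialized as an 8-bit grayscale PNG whose pixel values are the
#' class codes, so files round-trip exactly.
#'
#' @param path PNG file path.
#' @return `read_classmap()` returns an integer matrix; `write_classmap()`
#'   returns `path` invisibly.
#' @export
read_classmap <- function(path) {
  img <- png::readPNG(path)
  if (!is.matrix(img)) img <- img[, , 1]
  m <- round(img * 255)
  storage.mode(m) <- "integer"
  if (any(m < 0 | m > 3)) abort("Class-map PNG contains codes outside 0..3.")
  m
}

#' @rdname read_classmap
#' @param classmap Integer matrix with values in 0..3.
#' @export
write_classmap <- function(classmap, path) {
  check_classmap(classmap)
  png::writePNG(classmap / 255, target = path)
  invisible(path)
}

check_classmap <- function(classmap) {
  if (!is.matrix(classmap) || !is.numeric(classmap)) {
    abort("`classmap` must be an integer matrix.")
  }
  if (any(!classmap %in% 0:3)) {
    abort("`classmap` values must be class codes 0..3.")
  }
  invisible(classmap)
}

#' Save and load fitted pipeline models
#'
#' Models are stored as versioned RDS archives embedding the fitted model,
#' its hyperparameters, seed and training metadata, so a loaded model
#' reproduces its predictions exactly.
#'
#' @param model A `pixel_classifier` or `blob_classifier`.
#' @param path Destination `.rds` path.
#' @return `load_model()` returns the model; `save_model()` the path,
#'   invisibly.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, c("pixel_classifier", "blob_classifier"))) {
    abort("`model` must be a fitted tomascan classifier.")
  }
  saveRDS(list(format_version = 1L, class = class(model)[1], model = model),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) abort(paste0("No such model archive: ", path))
  arc <- readRDS(path)
  if (!is.list(arc) || is.null(arc$format_version) || is.null(arc$model)) {
    abort("Not a tomascan model archive.")
  }
  if (arc$format_version != 1L) {
    abort(paste0("Unsupported model archive version: ", arc$format_version))
  }
  arc$model
}
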