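#' Locate the fruit in a single-fruit blob
#'
#' The fruit position of a single-fruit blob is the center of gravity of
#' its mask (the arithmetic mean of member pixel coordinates), in image
#' coordinates.
#'
#' @param blob A one-row blob tibble (see [extract_blobs()]).
#' @return A one-row detection tibble: `row`, `col` (real-valued image
#'   coordinates), `source = "single_blob_centroid"`, `blob_id`.
#' @export
locate_single <- function(blob) {
  blob <- check_one_blob(blob)
  m <- blob$mask[[1]]
  if (!any(m)) abort("Blob mask is empty.")
  idx <- which(m, arr.ind = TRUE)
  tibble(
    row = mean(idx[, 1]) + blob$row0 - 1,
    col = mean(idx[, 2]) + blob$col0 - 1,
    source = "single_blob_centroid",
    blob_id = blob$blob_id
  )
}

#' Locate individual fruits in a multi-fruit blob
#'
#' Touching fruits segment into one blob, so individual positions are
#' recovered from the flash highlights: (1) the highlight map
#' `V * (1 - S)` of the blob patch; (2) [xmeans_1d()] over the map values
#' of the blob's member pixels; (3) keep the pixels of the cluster with
#' the highest mean map value; (4) 8-connected components of the kept
#' pixels, dropping components smaller than `min_region` pixels;
#' (5) one detection at each surviving component's center of gravity.
#'
#' @inheritParams locate_single
#' @param min_region Minimum highlight-component size in pixels;
#'   suppresses single-pixel glints.
#' @param kmax Cluster-count bound passed to [xmeans_1d()].
#' @param seed Seed recorded for provenance (the 1-D X-means is
#'   deterministic).
#' @return A detection tibble (possibly zero rows when no highlight
#'   region survives), `source = "multi_blob_highlight"`.
#' @export
locate_multi <- function(blob, min_region = 5, kmax = 20, seed = 1L) {
  blob <- check_one_blob(blob)
  m <- blob$mask[[1]]
  if (!any(m)) abort("Blob mask is empty.")
  hm <- highlight_map(blob$patch[[1]])
  vals <- hm[m]
  xm <- xmeans_1d(vals, kmax = kmax, seed = seed)
  top <- which.max(xm$cluster_means)
  keep <- matrix(FALSE, nrow(m), ncol(m))
  keep[m] <- xm$assignment == top
  lab <- label_components(keep)
  if (max(lab) == 0) return(empty_detection_tbl())
  dets <- purrr::map_dfr(seq_len(max(lab)), function(i) {
    idx <- which(lab == i, arr.ind = TRUE)
    if (nrow(idx) < min_region) return(NULL)
    tibble(
      row = mean(idx[, 1]) + blob$row0 - 1,
      col = mean(idx[, 2]) + blob$col0 - 1,
      source = "multi_blob_highlight",
      blob_id = blob$blob_id
    )
  })
  if (nrow(dets) == 0) empty_detection_tbl() else dets
}

empty_detection_tbl <- function() {
  tibble(row = double(), col = double(), source = character(),
         blob_id = integer())
}

#' Serialize detections
#'
#' `write_detections()` writes a detection tibble as CSV
#' (`image_id, row, col, source, blob_id`); `detections_geojson()`
#' renders it as a GeoJSON-style FeatureCollection of points
#' (x = column, y = row) with source and blob id as properties.
#'
#' @param detections A detection tibble.
#' @param path Output file path.
#' @param image_id Identifier recorded with each row/feature.
#' @return `write_detections()` returns `path` invisibly;
#'   `detections_geojson()` a JSON string.
#' @export
write_detections <- function(detections, path, image_id = "image") {
  out <- detections
  out$image_id <- image_id
  write.csv(out[c("image_id", "row", "col", "source", "blob_id")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections
#' @export
detections_geojson <- function(detections, image_id = "image") {
  features <- lapply(seq_len(nrow(detections)), function(i) {
    list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(detections$col[i], detections$row[i])),
      properties = list(image_id = image_id,
                        source = detections$source[i],
                        blob_id = detections$blob_id[i])
    )
  })
  jsonlite::toJSON(list(type = "FeatureCollection", features = features),
                   auto_unbox = TRUE, digits = NA)
}

check_one_blob <- function(blob) {
  if (!is.data.frame(blob) || nrow(blob) != 1 ||
      !all(c("row0", "col0", "mask", "patch", "blob_id") %in% names(blob))) {
    abort("`blob` must be a one-row blob tibble from extract_blobs().")
  }
  blob
}

#' Detect individual fruits in a canopy image
#'
#' Runs the full three-stage cascade: pixel segmentation
#' ([segment_pixels()]) -> blob extraction and classification
#' ([extract_blobs()], [classify_blobs()]) -> localization
#' ([locate_single()] / [locate_multi()]). Non-fruit blobs contribute
#' nothing. The result is fully reproducible given the fitted models and
#' seed.
#'
#' @param image An H x W x 3 RGB array in \[0, 255\].
#' @param pixel_clf A fitted `pixel_classifier`.
#' @param blob_clf A fitted `blob_classifier`.
#' @param min_region,kmax Passed to [locate_multi()].
#' @param seed Integer seed for provenance.
#' @return A detection tibble sorted row-major (`row`, then `col`), with
#'   attributes `n_candidates` (blobs before filtering) and
#'   `n_fruit_blobs` (blobs kept as single- or multi-fruit).
#' @export
detect_fruits <- function(image, pixel_clf, blob_clf, min_region = 5,
                          kmax = 20, seed = 1L) {
  classmap <- segment_pixels(pixel_clf, image)
  blobs <- extract_blobs(classmap, image)
  blobs <- classify_blobs(blob_clf, blobs)
  kept <- dplyr::filter(blobs, .data$blob_class != "non_fruit")
  dets <- empty_detection_tbl()
  if (nrow(kept) > 0) {
    dets <- purrr::map_dfr(seq_len(nrow(kept)), function(i) {
      b <- kept[i, ]
      if (b$blob_class == "single_fruit") {
        locate_single(b)
      } else {
        locate_multi(b, min_region = min_region, kmax = kmax, seed = seed)
      }
    })
  }
  dets <- dplyr::arrange(dets, .data$row, .data$col)
  attr(dets, "n_candidates") <- nrow(blobs)
  attr(dets, "n_fruit_blobs") <- nrow(kept)
  dets
}
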