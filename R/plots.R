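#' Plot detections over an image
#'
#' Overlays detections (crosses, colored by source) and, optionally,
#' ground-truth fruit disks on the RGB image.
#'
#' @param image An H x W x 3 RGB array in \[0, 255\].
#' @param detections A detection tibble (`row`, `col`, `source`).
#' @param truth Optional ground-truth tibble (`row`, `col`, `radius`,
#'   `stage`).
#' @return A ggplot object.
#' @export
plot_detections <- function(image, detections, truth = NULL) {
  check_rgb_image(image)
  H <- dim(image)[1]; W <- dim(image)[2]
  p <- ggplot2::ggplot() +
    ggplot2::annotation_raster(grDevices::as.raster(image / 255),
                               xmin = 0.5, xmax = W + 0.5,
                               ymin = 0.5, ymax = H + 0.5) +
    ggplot2::coord_fixed(xlim = c(0.5, W + 0.5), ylim = c(0.5, H + 0.5),
                         expand = FALSE) +
    ggplot2::theme_void()
  if (!is.null(truth) && nrow(truth) > 0) {
    circ <- purrr::map_dfr(seq_len(nrow(truth)), function(i) {
      th <- seq(0, 2 * pi, length.out = 60)
      tibble(id = i,
             x = truth$col[i] + truth$radius[i] * cos(th),
             y = H - (truth$row[i] + truth$radius[i] * sin(th)) + 1)
    })
    p <- p + ggplot2::geom_path(
      data = circ,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$id),
      color = "white", linewidth = 0.3, linetype = "22"
    )
  }
  if (nrow(detections) > 0) {
    pts <- tibble(x = detections$col, y = H - detections$row + 1,
                  source = detections$source)
    p <- p + ggplot2::geom_point(
      data = pts,
      ggplot2::aes(x = .data$x, y = .data$y, color = .data$source),
      shape = 4, size = 2, stroke = 1
    )
  }
  p
}
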