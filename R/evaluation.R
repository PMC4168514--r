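#' Match detections to ground-truth fruits
#'
#' Greedy one-to-one matching: a detection may match a fruit when it
#' falls inside that fruit's disk (distance from the fruit centroid at
#' most its radius). Candidate pairs are taken in increasing distance
#' order; each fruit and each detection is used at most once. The
#' matching radius comes from the ground truth, so it adapts to growth
#' stage.
#'
#' @param detections A detection tibble (`row`, `col`, ...), e.g. from
#'   [detect_fruits()].
#' @param truth A ground-truth tibble with `row`, `col`, `radius` and
#'   `stage` (one of young / immature / mature).
#' @return A `fruit_matching` object: list with `pairs` (tibble of
#'   `det`, `fruit`, `dist` index pairs), `n_detections`, `n_fruits`,
#'   `truth`, and index vectors `false_positives` (unmatched detections)
#'   and `false_negatives` (unmatched fruits).
#' @export
match_detections <- function(detections, truth) {
  detections <- as_tibble(detections)
  truth <- as_tibble(truth)
  check_truth(truth)
  nd <- nrow(detections)
  nf <- nrow(truth)
  pairs <- tibble(det = integer(), fruit = integer(), dist = double())
  if (nd > 0 && nf > 0) {
    d2 <- outer(detections$row, truth$row, "-")^2 +
      outer(detections$col, truth$col, "-")^2
    dist <- sqrt(d2)
    ok <- which(dist <= matrix(truth$radius, nd, nf, byrow = TRUE),
                arr.ind = TRUE)
    if (nrow(ok) > 0) {
      cand <- tibble(det = ok[, 1], fruit = ok[, 2],
                     dist = dist[ok])
      cand <- cand[order(cand$dist, cand$det, cand$fruit), ]
      used_d <- logical(nd); used_f <- logical(nf)
      keep <- logical(nrow(cand))
      for (i in seq_len(nrow(cand))) {
        if (!used_d[cand$det[i]] && !used_f[cand$fruit[i]]) {
          used_d[cand$det[i]] <- TRUE
          used_f[cand$fruit[i]] <- TRUE
          keep[i] <- TRUE
        }
      }
      pairs <- cand[keep, ]
    }
  }
  structure(
    list(
      pairs = pairs,
      n_detections = nd,
      n_fruits = nf,
      truth = truth,
      false_positives = setdiff(seq_len(nd), pairs$det),
      false_negatives = setdiff(seq_len(nf), pairs$fruit)
    ),
    class = "fruit_matching"
  )
}

check_truth <- function(truth) {
  need <- c("row", "col", "radius", "stage")
  if (!all(need %in% names(truth))) {
    abort(paste0("`truth` needs columns: ", paste(need, collapse = ", ")))
  }
  if (nrow(truth) > 0 && any(truth$radius <= 0)) abort("Radii must be positive.")
  if (!all(truth$stage %in% c("young", "immature", "mature"))) {
    abort("Stages must be young, immature or mature.")
  }
  invisible(truth)
}

#' @export
print.fruit_matching <- function(x, ...) {
  cat(sprintf("<fruit_matching: %d/%d fruits matched, %d/%d detections relevant>\n",
              nrow(x$pairs), x$n_fruits, nrow(x$pairs), x$n_detections))
  invisible(x)
}

#' Recall and precision of a matching
#'
#' Recall is the number of detected (matched) fruits divided by the
#' total number of fruits; precision is the number of relevant (matched)
#' detections divided by the total number of detections. `stage`
#' restricts recall to fruits of one growth stage. When the denominator
#' is zero the metric is undefined and `NA` is returned (reports leave
#' such cells absent rather than coercing them to 0 or 1).
#'
#' @param matching A `fruit_matching` from [match_detections()].
#' @param stage Optional growth stage filter for recall.
#' @return A number in \[0, 1\], or `NA` when undefined.
#' @export
recall <- function(matching, stage = NULL) {
  stopifnot(inherits(matching, "fruit_matching"))
  if (is.null(stage)) {
    total <- matching$n_fruits
    matched <- nrow(matching$pairs)
  } else {
    in_stage <- which(matching$truth$stage == stage)
    total <- length(in_stage)
    matched <- sum(matching$pairs$fruit %in% in_stage)
  }
  if (total == 0) return(NA_real_)
  matched / total
}

#' @rdname recall
#' @export
precision <- function(matching) {
  stopifnot(inherits(matching, "fruit_matching"))
  if (matching$n_detections == 0) return(NA_real_)
  nrow(matching$pairs) / matching$n_detections
}

#' Stage-stratified detection report
#'
#' Matches detections to ground truth and tabulates recall per growth
#' stage (with fruit counts), overall recall and precision. Undefined
#' metrics (no fruits of a stage, or no detections) are reported as `NA`.
#'
#' @inheritParams match_detections
#' @return A `detection_report`: list with `by_stage` (tibble of
#'   `stage`, `recall`, `n`), `recall`, `precision`, counts, and the
#'   underlying `matching`.
#' @export
detection_report <- function(detections, truth) {
  m <- match_detections(detections, truth)
  stages <- c("young", "immature", "mature")
  by_stage <- tibble(
    stage = stages,
    recall = unname(vapply(stages, function(s) recall(m, s), double(1))),
    n = unname(vapply(stages, function(s) sum(m$truth$stage == s), integer(1)))
  )
  structure(
    list(
      by_stage = by_stage,
      recall = recall(m),
      precision = precision(m),
      n_fruits = m$n_fruits,
      n_detections = m$n_detections,
      n_matched = nrow(m$pairs),
      matching = m
    ),
    class = "detection_report"
  )
}

#' @export
print.detection_report <- function(x, ...) {
  cat("Fruit detection report\n")
  cat(format_report_text(x))
  invisible(x)
}

# plain-text table mirroring the stage x {recall, n} layout
format_report_text <- function(x) {
  fmt <- function(v) if (is.na(v)) "-" else sprintf("%.2f", v)
  lines <- c(
    sprintf("  %-9s %7s %5s", "stage", "recall", "n"),
    sprintf("  %-9s %7s %5d", x$by_stage$stage,
            vapply(x$by_stage$recall, fmt, character(1)), x$by_stage$n),
    sprintf("  %-9s %7s %5d", "all", fmt(x$recall), x$n_fruits),
    sprintf("  precision %6s   (%d detections, %d matched)",
            fmt(x$precision), x$n_detections, x$n_matched)
  )
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' @describeIn detection_report `tidy()` returns the per-stage table plus
#'   an `all` row.
#' @param x,object A `detection_report`.
#' @param ... Unused.
#' @method tidy detection_report
#' @export
tidy.detection_report <- function(x, ...) {
  bind_rows(
    x$by_stage,
    tibble(stage = "all", recall = x$recall, n = x$n_fruits)
  )
}

#' @describeIn detection_report `glance()` returns a one-row summary.
#' @method glance detection_report
#' @export
glance.detection_report <- function(x, ...) {
  tibble(
    recall = x$recall, precision = x$precision,
    n_fruits = x$n_fruits, n_detections = x$n_detections,
    n_matched = x$n_matched
  )
}

#' @describeIn detection_report `autoplot()` draws recall by growth
#'   stage.
#' @method autoplot detection_report
#' @export
autoplot.detection_report <- function(object, ...) {
  df <- tidy(object)
  df$stage <- factor(df$stage, levels = c("young", "immature", "mature", "all"))
  ggplot2::ggplot(df[!is.na(df$recall), ],
                  ggplot2::aes(x = .data$stage, y = .data$recall)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("n=%d", .data$n)),
                       vjust = -0.4, size = 3) +
    ggplot2::scale_y_continuous(limits = c(0, 1.05)) +
    ggplot2::labs(x = NULL, y = "Recall",
                  title = "Recall by growth stage") +
    ggplot2::theme_minimal()
}

#' Split an image and its ground truth into vertical parts
#'
#' Crops the image into top / middle / bottom bands at the given cut
#' rows (half-open intervals: top is rows `[1, r1)`, middle `[r1, r2)`,
#' bottom `[r2, H]` in 1-based coordinates). Each fruit is assigned to
#' the band containing its centroid and its coordinates are shifted into
#' the band's frame, so per-part fruit counts always sum to the total.
#'
#' @param image An H x W x 3 RGB array.
#' @param truth Ground-truth tibble (`row`, `col`, `radius`, `stage`).
#' @param cut_rows Length-2 integer vector `(r1, r2)` with
#'   `1 < r1 < r2 <= H`.
#' @return A named list (`top`, `middle`, `bottom`) of lists, each with
#'   `image` and `truth`.
#' @export
partition_parts <- function(image, truth, cut_rows) {
  check_rgb_image(image)
  truth <- as_tibble(truth)
  check_truth(truth)
  H <- dim(image)[1]
  r1 <- cut_rows[1]; r2 <- cut_rows[2]
  if (length(cut_rows) != 2 || r1 <= 1 || r2 <= r1 || r2 > H) {
    abort("`cut_rows` must satisfy 1 < r1 < r2 <= image height.")
  }
  bands <- list(top = c(1, r1 - 1), middle = c(r1, r2 - 1), bottom = c(r2, H))
  lapply(bands, function(b) {
    sel <- truth$row >= b[1] & truth$row <= b[2]
    t2 <- truth[sel, ]
    t2$row <- t2$row - b[1] + 1
    list(image = image[b[1]:b[2], , , drop = FALSE], truth = t2)
  })
}
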