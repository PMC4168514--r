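#' Configuration of a synthetic flash-lit canopy scene
#'
#' Describes the scene geometry and photometry emulated by
#' [generate_scene()]: a near-black nighttime background, thin textured
#' brownish-green stems, green leaf ellipses (some with small specular
#' glints from the flash), disk-shaped fruits in three growth stages with
#' Lambertian-style shading and one off-center overexposed highlight per
#' fruit, fruit trusses of mutually tangent fruits, optional partial leaf
#' occlusion, impulse ("hot pixel") noise and additive Gaussian sensor
#' noise.
#'
#' Stage color families follow the field taxonomy: mature fruits red,
#' immature fruits pale green/whitish, young fruits small and dark green.
#' The young-fruit color is deliberately placed near the stem color so
#' the classic stem/young-fruit confusion of canopy imagery is present in
#' the benchmark, and stems carry strong per-pixel color texture so a
#' fraction of stem pixels falls on the fruit side of the pixel
#' classifier's boundary — the mechanism that produces the large
#' candidate-blob counts the blob stage must eliminate.
#'
#' @param width,height Image size in pixels.
#' @param n_young,n_immature,n_mature Isolated (single-fruit) counts per
#'   stage.
#' @param n_trusses Number of multi-fruit trusses.
#' @param fruits_per_truss Length-2 range; each truss size is drawn
#'   uniformly from it.
#' @param truss_overlap Pixels of overlap between adjacent truss fruits
#'   (guarantees one 8-connected fruit region per truss).
#' @param radius_young,radius_immature,radius_mature Length-2 radius
#'   ranges (pixels) per stage.
#' @param highlight_frac Highlight radius as a fraction of fruit radius
#'   (floor 2 px).
#' @param n_leaves,n_stems Foliage counts.
#' @param glint_prob Probability that a leaf carries a small specular
#'   glint.
#' @param occlusion Probability that a fruit is partially occluded by a
#'   leaf drawn over it.
#' @param noise_sd Gaussian sensor-noise standard deviation (8-bit
#'   counts).
#' @param salt_prob Per-pixel probability of an impulse (bright random)
#'   pixel.
#' @param colors Named list of `c(R, G, B)` means for `background`,
#'   `stem`, `leaf`, `young`, `immature`, `mature`, `highlight`.
#' @return A `scene_config` list.
#' @export
scene_config <- function(width = 320, height = 240,
                         n_young = 2, n_immature = 3, n_mature = 2,
                         n_trusses = 1, fruits_per_truss = c(2, 4),
                         truss_overlap = 2,
                         radius_young = c(4, 7),
                         radius_immature = c(9, 14),
                         radius_mature = c(10, 16),
                         highlight_frac = 0.28,
                         n_leaves = 8, n_stems = 2, glint_prob = 0.3,
                         occlusion = 0, noise_sd = 2, salt_prob = 0.0015,
                         colors = list(
                           background = c(10, 10, 14),
                           stem = c(95, 110, 58),
                           leaf = c(50, 130, 55),
                           young = c(80, 105, 60),
                           immature = c(190, 205, 160),
                           mature = c(205, 45, 40),
                           highlight = c(250, 250, 246)
                         )) {
  cfg <- list(
    width = width, height = height,
    n_young = n_young, n_immature = n_immature, n_mature = n_mature,
    n_trusses = n_trusses, fruits_per_truss = fruits_per_truss,
    truss_overlap = truss_overlap,
    radius_young = radius_young, radius_immature = radius_immature,
    radius_mature = radius_mature,
    highlight_frac = highlight_frac,
    n_leaves = n_leaves, n_stems = n_stems, glint_prob = glint_prob,
    occlusion = occlusion, noise_sd = noise_sd, salt_prob = salt_prob,
    colors = colors
  )
  validate_scene_config(cfg)
  structure(cfg, class = "scene_config")
}

validate_scene_config <- function(cfg) {
  counts <- c(cfg$n_young, cfg$n_immature, cfg$n_mature, cfg$n_trusses,
              cfg$n_leaves, cfg$n_stems)
  if (any(counts < 0)) abort("Scene counts must be non-negative.")
  if (cfg$noise_sd < 0 || cfg$salt_prob < 0 || cfg$occlusion < 0 ||
      cfg$occlusion > 1) {
    abort("noise_sd/salt_prob must be >= 0 and occlusion in [0, 1].")
  }
  radii <- c(cfg$radius_young, cfg$radius_immature, cfg$radius_mature)
  if (any(radii <= 0)) abort("Fruit radii must be positive.")
  need <- c("background", "stem", "leaf", "young", "immature", "mature",
            "highlight")
  if (!all(need %in% names(cfg$colors))) {
    abort(paste0("`colors` needs entries: ", paste(need, collapse = ", ")))
  }
  invisible(cfg)
}

# one root seed -> independent per-purpose streams, all below 2^31
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1000003 + i) %% 2147483629)
}

#' Generate a synthetic canopy scene with exact ground truth
#'
#' Renders a flash-lit nighttime canopy scene per a [scene_config()] and
#' returns the image together with its exact pixel-level class map and
#' fruit list. Generation is bit-reproducible: the same config and seed
#' always give the same scene. Paint order is background, stems, leaves,
#' fruits (with highlights), then occluding leaves, so every unoccluded
#' fruit pixel is labeled fruit in the class map.
#'
#' @param config A [scene_config()].
#' @param seed Integer seed.
#' @return A `canopy_scene`: list with `image` (H x W x 3, \[0, 255\]),
#'   `classmap` (integer matrix, codes per [class_levels()]), `fruits`
#'   (tibble: `fruit_id`, `row`, `col`, `radius`, `stage`, `truss_id`,
#'   `hl_row`, `hl_col` — the highlight center), `config`, `seed`.
#' @export
generate_scene <- function(config = scene_config(), seed = 1L) {
  validate_scene_config(config)
  set.seed(derive_seed(seed, 0))
  H <- config$height; W <- config$width
  img <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) img[, , ch] <- config$colors$background[ch]
  img <- img + array(rnorm(H * W * 3, 0, 2), dim = c(H, W, 3))
  cm <- matrix(0L, H, W)

  scene <- list(img = img, cm = cm, H = H, W = W, cfg = config)
  scene <- draw_stems(scene)
  scene <- draw_leaves(scene)
  scene <- place_and_draw_fruits(scene)
  scene <- apply_occlusion(scene)
  scene <- apply_sensor_noise(scene)

  structure(
    list(image = scene$img, classmap = scene$cm, fruits = scene$fruits,
         config = config, seed = as.integer(seed)),
    class = "canopy_scene"
  )
}

#' @export
print.canopy_scene <- function(x, ...) {
  cat(sprintf("<canopy_scene %dx%d: %d fruits (%s), seed %d>\n",
              x$config$height, x$config$width, nrow(x$fruits),
              paste(sprintf("%d %s", table(x$fruits$stage)[unique(x$fruits$stage)],
                            unique(x$fruits$stage)), collapse = ", "),
              x$seed))
  invisible(x)
}

# ---- rendering primitives -------------------------------------------------

# stamp a filled disk: per-pixel color = base + shading + jitter
stamp_disk <- function(scene, cr, cc, radius, color, code,
                       pixel_sd = 3, shade = FALSE) {
  r0 <- max(1, floor(cr - radius)); r1 <- min(scene$H, ceiling(cr + radius))
  c0 <- max(1, floor(cc - radius)); c1 <- min(scene$W, ceiling(cc + radius))
  if (r0 > r1 || c0 > c1) return(scene)
  rr <- r0:r1; cc2 <- c0:c1
  d2 <- outer((rr - cr)^2, (cc2 - cc)^2, "+")
  inside <- d2 <= radius^2
  idx <- which(inside, arr.ind = TRUE)
  if (nrow(idx) == 0) return(scene)
  gain <- if (shade) {
    0.78 + 0.22 * sqrt(pmax(0, 1 - d2[inside] / radius^2))
  } else rep(1, nrow(idx))
  rows <- rr[idx[, 1]]; cols <- cc2[idx[, 2]]
  for (ch in 1:3) {
    scene$img[cbind(rows, cols, ch)] <-
      color[ch] * gain + rnorm(length(rows), 0, pixel_sd)
  }
  scene$cm[cbind(rows, cols)] <- code
  scene
}

stamp_ellipse <- function(scene, cr, cc, a, b, theta, color, code,
                          pixel_sd = 5) {
  ext <- max(a, b)
  r0 <- max(1, floor(cr - ext)); r1 <- min(scene$H, ceiling(cr + ext))
  c0 <- max(1, floor(cc - ext)); c1 <- min(scene$W, ceiling(cc + ext))
  if (r0 > r1 || c0 > c1) return(scene)
  rr <- r0:r1; cc2 <- c0:c1
  dy <- outer(rr - cr, rep(1, length(cc2)))
  dx <- outer(rep(1, length(rr)), cc2 - cc)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  idx <- which(inside, arr.ind = TRUE)
  if (nrow(idx) == 0) return(scene)
  rows <- rr[idx[, 1]]; cols <- cc2[idx[, 2]]
  for (ch in 1:3) {
    scene$img[cbind(rows, cols, ch)] <-
      color[ch] + rnorm(length(rows), 0, pixel_sd)
  }
  scene$cm[cbind(rows, cols)] <- code
  scene
}

draw_stems <- function(scene) {
  cfg <- scene$cfg
  if (cfg$n_stems == 0) return(scene)
  for (s in seq_len(cfg$n_stems)) {
    x0 <- runif(1, 0.15, 0.85) * scene$W
    amp <- runif(1, 3, 12)
    phase <- runif(1, 0, 2 * pi)
    halfw <- runif(1, 1.5, 2.5)
    for (row in seq(1, scene$H, by = 1)) {
      col <- x0 + amp * sin(phase + row / 40)
      scene <- stamp_disk(scene, row, col, halfw, cfg$colors$stem, 3L,
                          pixel_sd = 14)
    }
  }
  scene
}

draw_leaves <- function(scene) {
  cfg <- scene$cfg
  if (cfg$n_leaves == 0) return(scene)
  for (l in seq_len(cfg$n_leaves)) {
    cr <- runif(1, 1, scene$H); cc <- runif(1, 1, scene$W)
    a <- runif(1, 12, 30); b <- runif(1, 6, 15)
    theta <- runif(1, 0, pi)
    col <- cfg$colors$leaf + rnorm(3, 0, 10)
    scene <- stamp_ellipse(scene, cr, cc, a, b, theta, col, 2L)
    if (runif(1) < cfg$glint_prob) {
      # flash glint on the leaf: small overexposed spot (still leaf class)
      gr <- cr + runif(1, -b / 2, b / 2); gc <- cc + runif(1, -a / 2, a / 2)
      scene <- stamp_disk(scene, gr, gc, runif(1, 1, 2),
                          cfg$colors$highlight, 2L, pixel_sd = 2)
    }
  }
  scene
}

stage_radius <- function(cfg, stage) {
  rng <- switch(stage, young = cfg$radius_young,
                immature = cfg$radius_immature, mature = cfg$radius_mature)
  runif(1, rng[1], rng[2])
}

# rejection placement: keep `clearance` px between circle borders
# (per-obstacle `clearance` column when present, else 3)
place_circle <- function(placed, H, W, radius, near = NULL, dist_to = NULL,
                         tries = 200) {
  clr <- if ("clearance" %in% names(placed)) placed$clearance else rep(3, nrow(placed))
  for (t in seq_len(tries)) {
    if (is.null(near)) {
      cr <- runif(1, radius + 2, H - radius - 2)
      cc <- runif(1, radius + 2, W - radius - 2)
    } else {
      ang <- runif(1, 0, 2 * pi)
      cr <- near[1] + dist_to * sin(ang)
      cc <- near[2] + dist_to * cos(ang)
      if (cr < radius + 2 || cr > H - radius - 2 ||
          cc < radius + 2 || cc > W - radius - 2) next
    }
    ok <- TRUE
    if (nrow(placed) > 0) {
      gap <- sqrt((placed$row - cr)^2 + (placed$col - cc)^2) -
        (placed$radius + radius)
      ok <- all(gap >= clr)
    }
    if (ok) return(c(cr, cc))
  }
  NULL
}

place_and_draw_fruits <- function(scene) {
  cfg <- scene$cfg
  fruits <- tibble(fruit_id = integer(), row = double(), col = double(),
                   radius = double(), stage = character(),
                   truss_id = integer(), hl_row = double(), hl_col = double())
  placed <- tibble(row = double(), col = double(), radius = double())
  fid <- 0L

  add_fruit <- function(cr, cc, radius, stage, truss_id) {
    fid <<- fid + 1L
    base <- cfg$colors[[stage]] + rnorm(3, 0, if (stage == "young") 6 else 8)
    scene <<- stamp_disk(scene, cr, cc, radius, base, 1L, pixel_sd = 3,
                         shade = TRUE)
    hlr <- max(2, cfg$highlight_frac * radius)
    off <- max(0, radius - hlr - 1) * 0.5
    ang <- runif(1, 0, 2 * pi)
    hr <- cr + off * sin(ang); hc <- cc + off * cos(ang)
    scene <<- stamp_disk(scene, hr, hc, hlr, cfg$colors$highlight, 1L,
                         pixel_sd = 2)
    fruits <<- bind_rows(fruits, tibble(
      fruit_id = fid, row = cr, col = cc, radius = radius, stage = stage,
      truss_id = truss_id, hl_row = hr, hl_col = hc
    ))
  }

  # trusses first (they need the most room)
  for (t in seq_len(cfg$n_trusses)) {
    rng <- cfg$fruits_per_truss
    k <- rng[1] + sample.int(rng[2] - rng[1] + 1, 1) - 1
    stage <- sample(c("immature", "mature"), 1, prob = c(0.7, 0.3))
    radii <- vapply(seq_len(k), function(i) stage_radius(cfg, stage), double(1))
    pos <- place_circle(placed, scene$H, scene$W, sum(radii))
    if (is.null(pos)) abort("Could not place a truss within the scene.",
                            class = "tomascan_placement_error")
    centers <- matrix(pos, 1, 2)
    for (i in seq_len(k)[-1]) {
      d <- radii[i - 1] + radii[i] - cfg$truss_overlap
      # the new fruit is tangent to its predecessor; non-adjacent truss
      # members must not interpenetrate (>= 1 px border gap) so no fruit
      # can cover a neighbor's highlight
      obstacles <- bind_rows(
        tibble(row = placed$row, col = placed$col, radius = placed$radius,
               clearance = 3),
        if (i > 2) tibble(row = centers[seq_len(i - 2), 1],
                          col = centers[seq_len(i - 2), 2],
                          radius = radii[seq_len(i - 2)], clearance = 1)
      )
      p <- place_circle(obstacles, scene$H, scene$W, radii[i],
                        near = centers[i - 1, ], dist_to = d)
      if (is.null(p)) abort("Could not place a truss within the scene.",
                            class = "tomascan_placement_error")
      centers <- rbind(centers, p)
    }
    for (i in seq_len(k)) {
      add_fruit(centers[i, 1], centers[i, 2], radii[i], stage, t)
    }
    placed <- bind_rows(placed, tibble(row = centers[, 1], col = centers[, 2],
                                       radius = radii))
  }

  # isolated fruits
  singles <- c(rep("mature", cfg$n_mature), rep("immature", cfg$n_immature),
               rep("young", cfg$n_young))
  for (stage in singles) {
    radius <- stage_radius(cfg, stage)
    pos <- place_circle(placed, scene$H, scene$W, radius)
    if (is.null(pos)) abort("Could not place an isolated fruit.",
                            class = "tomascan_placement_error")
    add_fruit(pos[1], pos[2], radius, stage, NA_integer_)
    placed <- bind_rows(placed, tibble(row = pos[1], col = pos[2],
                                       radius = radius))
  }
  scene$fruits <- fruits
  scene
}

apply_occlusion <- function(scene) {
  cfg <- scene$cfg
  if (cfg$occlusion == 0 || nrow(scene$fruits) == 0) return(scene)
  for (i in seq_len(nrow(scene$fruits))) {
    if (runif(1) >= cfg$occlusion) next
    f <- scene$fruits[i, ]
    # leaf covering roughly one side of the fruit
    ang <- runif(1, 0, 2 * pi)
    cr <- f$row + f$radius * 0.9 * sin(ang)
    cc <- f$col + f$radius * 0.9 * cos(ang)
    col <- cfg$colors$leaf + rnorm(3, 0, 10)
    scene <- stamp_ellipse(scene, cr, cc, f$radius * runif(1, 0.8, 1.2),
                           f$radius * runif(1, 0.5, 0.9), runif(1, 0, pi),
                           col, 2L)
  }
  scene
}

apply_sensor_noise <- function(scene) {
  cfg <- scene$cfg
  H <- scene$H; W <- scene$W
  if (cfg$salt_prob > 0) {
    hot <- which(runif(H * W) < cfg$salt_prob)
    if (length(hot) > 0) {
      for (ch in 1:3) {
        plane <- scene$img[, , ch]
        plane[hot] <- runif(length(hot), 80, 255)
        scene$img[, , ch] <- plane
      }
    }
  }
  if (cfg$noise_sd > 0) {
    scene$img <- scene$img + array(rnorm(H * W * 3, 0, cfg$noise_sd),
                                   dim = c(H, W, 3))
  }
  scene$img <- round(pmin(pmax(scene$img, 0), 255))
  scene
}

#' @describeIn generate_scene `autoplot()` renders the scene with
#'   ground-truth fruit outlines.
#' @param object A `canopy_scene`.
#' @param ... Unused.
#' @method autoplot canopy_scene
#' @export
autoplot.canopy_scene <- function(object, ...) {
  img <- object$image / 255
  H <- dim(img)[1]; W <- dim(img)[2]
  raster <- grDevices::as.raster(img)
  circ <- purrr::map_dfr(seq_len(nrow(object$fruits)), function(i) {
    f <- object$fruits[i, ]
    th <- seq(0, 2 * pi, length.out = 60)
    tibble(fruit_id = f$fruit_id, stage = f$stage,
           x = f$col + f$radius * cos(th),
           y = H - (f$row + f$radius * sin(th)) + 1)
  })
  p <- ggplot2::ggplot() +
    ggplot2::annotation_raster(raster, xmin = 0.5, xmax = W + 0.5,
                               ymin = 0.5, ymax = H + 0.5) +
    ggplot2::coord_fixed(xlim = c(0.5, W + 0.5), ylim = c(0.5, H + 0.5),
                         expand = FALSE) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_void()
  if (nrow(circ) > 0) {
    p <- p + ggplot2::geom_path(
      data = circ,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$fruit_id,
                   color = .data$stage),
      linewidth = 0.4
    )
  }
  p
}

#' Sample a labeled pixel training set from synthetic scenes
#'
#' Generates fresh scenes (seeds derived from the root seed) and samples
#' exactly `n_per_class` pixels from each class's ground-truth region,
#' pooling scenes until every class is filled. Background, leaf and stem
#' pixels are drawn uniformly from their regions. Fruit pixels are drawn
#' per fruit (each fruit contributes equally, regardless of its area),
#' emulating an annotator who deliberately labels fruits of every growth
#' stage; uniform-area sampling would leave the small young fruits almost
#' unrepresented.
#'
#' @param config A [scene_config()].
#' @param n_per_class Pixels per class (the field-scale reference is
#'   140,000 fruit and 100,000 per other class; scale to taste).
#' @param seed Integer root seed.
#' @param max_scenes Safety cap on scenes generated.
#' @return A tibble: `scene`, `row`, `col`, `label` and the 15 feature
#'   columns; `4 * n_per_class` rows when `n_per_class` is scalar, or a
#'   named vector (names from [class_levels()]) for unequal counts.
#' @export
generate_pixel_training_set <- function(config = scene_config(), n_per_class,
                                        seed = 1L, max_scenes = 100) {
  if (length(n_per_class) == 1) {
    n_per_class <- stats::setNames(rep(n_per_class, 4), CLASS_LEVELS)
  }
  if (!all(CLASS_LEVELS %in% names(n_per_class))) {
    abort("`n_per_class` must be scalar or named by the four classes.")
  }
  need <- n_per_class[CLASS_LEVELS]
  out <- list()
  for (i in seq_len(max_scenes)) {
    if (all(need <= 0)) break
    sc <- generate_scene(config, seed = derive_seed(seed, i))
    set.seed(derive_seed(seed, 10000 + i))
    for (code in 0:3) {
      cls <- CLASS_LEVELS[code + 1]
      if (need[cls] <= 0) next
      pix <- which(sc$classmap == code)
      if (length(pix) == 0) next
      take <- min(need[cls], length(pix))
      sel <- if (code == 1L) {
        sample_fruit_pixels(sc, take)
      } else {
        sample(pix, take)
      }
      rr <- (sel - 1) %% nrow(sc$classmap) + 1
      cc <- (sel - 1) %/% nrow(sc$classmap) + 1
      rgb <- cbind(sc$image[cbind(rr, cc, 1)], sc$image[cbind(rr, cc, 2)],
                   sc$image[cbind(rr, cc, 3)])
      out[[length(out) + 1]] <- dplyr::bind_cols(
        tibble(scene = i, row = rr, col = cc, label = cls),
        pixel_features(rgb)
      )
      need[cls] <- need[cls] - take
    }
  }
  if (any(need > 0)) {
    abort(paste0("Could not collect enough pixels for: ",
                 paste(names(need)[need > 0], collapse = ", ")),
          class = "tomascan_sampling_error")
  }
  bind_rows(out)
}

# draw n fruit pixels, cycling over fruits so each contributes equally
sample_fruit_pixels <- function(sc, n) {
  H <- nrow(sc$classmap)
  per_fruit <- lapply(seq_len(nrow(sc$fruits)), function(i) {
    f <- sc$fruits[i, ]
    r0 <- max(1, floor(f$row - f$radius)); r1 <- min(H, ceiling(f$row + f$radius))
    c0 <- max(1, floor(f$col - f$radius))
    c1 <- min(ncol(sc$classmap), ceiling(f$col + f$radius))
    sub <- sc$classmap[r0:r1, c0:c1] == 1L
    idx <- which(sub, arr.ind = TRUE)
    (idx[, 2] + c0 - 2) * H + idx[, 1] + r0 - 1   # linear indices
  })
  per_fruit <- per_fruit[lengths(per_fruit) > 0]
  if (length(per_fruit) == 0) return(sample(which(sc$classmap == 1L), n))
  quota <- rep(ceiling(n / length(per_fruit)), length(per_fruit))
  picks <- unlist(lapply(seq_along(per_fruit), function(i) {
    pool <- per_fruit[[i]]
    sample(pool, min(quota[i], length(pool)))
  }))
  if (length(picks) >= n) sample(picks, n) else {
    c(picks, sample(which(sc$classmap == 1L), n - length(picks)))
  }
}

#' Build a labeled blob training set from synthetic scenes
#'
#' Generates scenes and harvests candidate blobs from them, labeled
#' exactly from the ground truth: a blob containing two or more
#' ground-truth fruit centers is `multi_fruit`, exactly one
#' `single_fruit`, none `non_fruit`.
#'
#' When `pixel_classifier` is supplied, blobs come from that
#' classifier's own segmentation of the scenes — the same distribution
#' the blob classifier will face at detection time, including ragged
#' fruit outlines and the many few-pixel false-positive components that
#' pixel misclassification produces. Without a classifier, blobs come
#' from the ground-truth class map with small speckle components
#' injected into the fruit class as a stand-in for that misclassified-
#' pixel noise.
#'
#' @param config A [scene_config()].
#' @param counts Named or positional counts `c(multi, single, non)`
#'   (field-scale reference 30 / 200 / 2000).
#' @param pixel_classifier Optional fitted [train_pixel_classifier()]
#'   model used to produce the candidate blobs.
#' @param seed Integer root seed.
#' @param speckles_per_scene Injected speckle components per scene
#'   (ground-truth mode only).
#' @param max_scenes Safety cap.
#' @return A list: `features` (tibble of 19 features + `blob_class`),
#'   `blobs` (the labeled blob tibble, `scene` column added).
#' @export
generate_blob_training_set <- function(config = scene_config(), counts,
                                       pixel_classifier = NULL,
                                       seed = 1L, speckles_per_scene = 40,
                                       max_scenes = 400) {
  counts <- as.integer(counts)
  if (length(counts) != 3) abort("`counts` must be c(multi, single, non).")
  need <- stats::setNames(counts, BLOB_CLASS_LEVELS)
  feats <- list(); blobs_out <- list()
  for (i in seq_len(max_scenes)) {
    if (all(need <= 0)) break
    sc <- generate_scene(config, seed = derive_seed(seed, 20000 + i))
    cm <- if (is.null(pixel_classifier)) {
      inject_speckles(sc$classmap, speckles_per_scene,
                      derive_seed(seed, 30000 + i))
    } else {
      segment_pixels(pixel_classifier, sc$image)
    }
    blobs <- extract_blobs(cm, sc$image)
    if (nrow(blobs) == 0) next
    lab <- label_blobs_by_truth(blobs, sc$fruits)
    fts <- blob_features(blobs)
    for (cls in BLOB_CLASS_LEVELS) {
      sel <- which(lab == cls)
      if (length(sel) == 0 || need[cls] <= 0) next
      take <- sel[seq_len(min(need[cls], length(sel)))]
      f2 <- fts[take, ]
      f2$blob_class <- cls
      feats[[length(feats) + 1]] <- f2
      b2 <- blobs[take, ]
      b2$blob_class <- cls
      b2$scene <- i
      blobs_out[[length(blobs_out) + 1]] <- b2
      need[cls] <- need[cls] - length(take)
    }
  }
  if (any(need > 0)) {
    abort(paste0("Could not collect enough blobs for: ",
                 paste(names(need)[need > 0], collapse = ", ")),
          class = "tomascan_sampling_error")
  }
  list(features = bind_rows(feats), blobs = bind_rows(blobs_out))
}

# add small fruit-class speckle components (1-4 px) at non-fruit positions
inject_speckles <- function(classmap, n, seed) {
  set.seed(seed)
  H <- nrow(classmap); W <- ncol(classmap)
  cm <- classmap
  placed <- 0
  guard <- 0
  while (placed < n && guard < n * 50) {
    guard <- guard + 1
    r <- sample.int(H - 3, 1) + 1
    c <- sample.int(W - 3, 1) + 1
    # keep clear of existing fruit pixels so speckles stay separate blobs
    if (any(cm[max(1, r - 2):min(H, r + 2), max(1, c - 2):min(W, c + 2)] == 1L)) next
    sz <- sample(1:4, 1)
    rr <- r; cc <- c
    cm[r, c] <- 1L
    for (s in seq_len(sz - 1)) {
      rr <- min(max(rr + sample(-1:1, 1), 1), H)
      cc <- min(max(cc + sample(-1:1, 1), 1), W)
      cm[rr, cc] <- 1L
    }
    placed <- placed + 1
  }
  cm
}

# blob label from the number of ground-truth fruit centers inside its mask
label_blobs_by_truth <- function(blobs, fruits) {
  vapply(seq_len(nrow(blobs)), function(i) {
    b <- blobs[i, ]
    if (nrow(fruits) == 0) return("non_fruit")
    fr <- round(fruits$row) - b$row0 + 1
    fc <- round(fruits$col) - b$col0 + 1
    inb <- fr >= 1 & fr <= b$height & fc >= 1 & fc <= b$width
    n_in <- 0L
    if (any(inb)) {
      m <- b$mask[[1]]
      n_in <- sum(m[cbind(fr[inb], fc[inb])])
    }
    if (n_in >= 2) "multi_fruit" else if (n_in == 1) "single_fruit" else "non_fruit"
  }, character(1))
}
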