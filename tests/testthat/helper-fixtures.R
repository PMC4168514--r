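# Shared fixtures. Everything is generated in code; the expensive fitted
# models are built once per test run and memoized here.

.fixture_env <- new.env(parent = emptyenv())

# a small uniform-color image
flat_image <- function(h, w, rgb) {
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- rgb[ch]
  img
}

# scene config for fast unit tests: small canvas, same photometry
tiny_scene_config <- function(...) {
  base <- list(width = 160, height = 120, n_young = 1, n_immature = 1,
               n_mature = 1, n_trusses = 1, fruits_per_truss = c(2, 3),
               n_leaves = 4, n_stems = 1)
  do.call(scene_config, utils::modifyList(base, list(...)))
}

# truss-only scene for localization tests: noiseless, no foliage
truss_scene_config <- function(...) {
  base <- list(width = 200, height = 160, n_young = 0, n_immature = 0,
               n_mature = 0, n_trusses = 1, fruits_per_truss = c(2, 5),
               n_leaves = 0, n_stems = 0, noise_sd = 0, salt_prob = 0,
               glint_prob = 0)
  do.call(scene_config, utils::modifyList(base, list(...)))
}

# well-separated 4-class color clusters in feature space (no rendering)
separable_pixel_samples <- function(n_per_class = 120, sd = 4, seed = 42) {
  set.seed(seed)
  means <- list(background = c(10, 10, 15), fruit = c(210, 40, 40),
                leaf = c(40, 140, 50), stem = c(150, 120, 70))
  purrr::map_dfr(names(means), function(cls) {
    rgb <- matrix(rep(means[[cls]], each = n_per_class), ncol = 3) +
      matrix(rnorm(3 * n_per_class, 0, sd), ncol = 3)
    rgb <- pmin(pmax(rgb, 0), 255)
    dplyr::bind_cols(tibble::tibble(label = cls), pixel_features(rgb))
  })
}

# models trained under the package's standard study conditions,
# memoized across test files
study_models <- function() {
  if (!is.null(.fixture_env$models)) return(.fixture_env$models)
  scfg <- scene_config()
  px <- generate_pixel_training_set(
    scfg, c(background = 1000, fruit = 1400, leaf = 1000, stem = 1000),
    seed = 2024
  )
  pixel_clf <- train_pixel_classifier(px, seed = 2025)
  bl <- generate_blob_training_set(scfg, counts = c(30, 200, 2000),
                                   pixel_classifier = pixel_clf, seed = 2026)
  blob_clf <- train_blob_classifier(bl$features, bl$features$blob_class,
                                    seed = 2027)
  .fixture_env$models <- list(pixel = pixel_clf, blob = blob_clf,
                              scene_config = scfg)
  .fixture_env$models
}
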