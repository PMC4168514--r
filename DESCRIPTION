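Package: tomascan
Title: On-Plant Tomato Fruit Detection in Flash-Lit Canopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-stage pipeline for detecting individual tomato fruits
    (young, immature and mature) in RGB images of greenhouse canopies taken
    with on-camera flash. Stage one classifies every pixel into fruit, leaf,
    stem or background with a CART decision tree over 15 color features drawn
    from five color spaces. Stage two extracts connected fruit-pixel blobs,
    summarises each by 19 color, texture, size and shape features, and removes
    false positives with a random-forest blob classifier. Stage three locates
    individual fruits: single-fruit blobs by their centroid, multi-fruit
    clusters by X-means clustering of a specular-highlight map built from the
    HSV value and inverted saturation channels. Includes a seeded synthetic
    canopy-scene generator with exact ground truth, stage-stratified
    recall/precision evaluation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    randomForest,
    rlang,
    rpart,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    cluster,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
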