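truth_tbl <- function(...) {
  tibble::as_tibble(data.frame(...))
}

dets_tbl <- function(rows, cols) {
  tibble::tibble(row = rows, col = cols, source = "single_blob_centroid",
                 blob_id = seq_along(rows))
}

test_that("greedy within-disk matching behaves on the canonical cases", {
  truth <- truth_tbl(row = 50, col = 50, radius = 10, stage = "mature")

  # detection at the centroid matches
  m <- match_detections(dets_tbl(50, 50), truth)
  expect_equal(nrow(m$pairs), 1)

  # two detections inside one fruit: one match, one false positive
  m2 <- match_detections(dets_tbl(c(50, 52), c(50, 51)), truth)
  expect_equal(nrow(m2$pairs), 1)
  expect_equal(length(m2$false_positives), 1)
  expect_equal(m2$pairs$det, 1)   # the closer one wins

  # a detection outside every disk never matches
  m3 <- match_detections(dets_tbl(80, 80), truth)
  expect_equal(nrow(m3$pairs), 0)
  expect_equal(m3$false_negatives, 1)
})

test_that("greedy matching attains the exhaustive optimum on toy configs", {
  set.seed(17)
  for (rep in 1:40) {
    nf <- sample(1:4, 1); nd <- sample(1:4, 1)
    # non-overlapping fruits on a coarse grid; radius below half spacing
    cells <- sample(1:9, nf)
    truth <- truth_tbl(
      row = 30 * ((cells - 1) %/% 3) + 15,
      col = 30 * ((cells - 1) %% 3) + 15,
      radius = runif(nf, 4, 10),
      stage = sample(c("young", "immature", "mature"), nf, replace = TRUE)
    )
    dets <- dets_tbl(runif(nd, 0, 90), runif(nd, 0, 90))
    m <- match_detections(dets, truth)
    best <- oracle_assignment(dets, truth)
    expect_equal(nrow(m$pairs), best$n)
    if (nrow(m$pairs) > 0) {
      expect_equal(sum(m$pairs$dist), best$cost, tolerance = 1e-9)
    }
  }
})

test_that("recall and precision follow the defining ratios", {
  # 8 of 10 fruits matched -> recall 0.8
  truth <- truth_tbl(row = seq(10, 100, by = 10), col = 50, radius = 3,
                     stage = c(rep("young", 9), "mature"))
  dets <- dets_tbl(seq(10, 80, by = 10), rep(50, 8))
  m <- match_detections(dets, truth)
  expect_equal(recall(m), 0.8)
  expect_equal(precision(m), 1.0)

  # 7 relevant of 8 detections -> precision 0.875
  dets2 <- dets_tbl(c(seq(10, 70, by = 10), 500), c(rep(50, 7), 500))
  m2 <- match_detections(dets2, truth)
  expect_equal(precision(m2), 0.875)
  expect_equal(recall(m2), 0.7)

  # stage filter: 7 of 9 young matched
  expect_equal(recall(m2, "young"), 7 / 9)
  expect_equal(recall(m2, "mature"), 0)

  # all matched
  dets3 <- dets_tbl(seq(10, 100, by = 10), rep(50, 10))
  expect_equal(recall(match_detections(dets3, truth)), 1.0)
})

test_that("undefined metrics are NA, never 0 or 1", {
  no_truth <- truth_tbl(row = numeric(0), col = numeric(0),
                        radius = numeric(0), stage = character(0))
  m <- match_detections(dets_tbl(5, 5), no_truth)
  expect_true(is.na(recall(m)))
  expect_equal(precision(m), 0)
  m2 <- match_detections(dets_tbl(numeric(0), numeric(0)),
                         truth_tbl(row = 5, col = 5, radius = 2,
                                   stage = "young"))
  expect_true(is.na(precision(m2)))
  expect_equal(recall(m2), 0)
  # stage absent from the truth -> NA in the report
  rep <- detection_report(dets_tbl(5, 5),
                          truth_tbl(row = 5, col = 5, radius = 2,
                                    stage = "young"))
  expect_true(is.na(rep$by_stage$recall[rep$by_stage$stage == "mature"]))
  expect_equal(rep$by_stage$recall[rep$by_stage$stage == "young"], 1)
})

test_that("metrics are permutation invariant and move the right way", {
  set.seed(23)
  truth <- truth_tbl(row = runif(6, 0, 100), col = runif(6, 0, 100),
                     radius = 5, stage = "immature")
  dets <- dets_tbl(truth$row[1:4] + runif(4, -2, 2),
                   truth$col[1:4] + runif(4, -2, 2))
  m <- match_detections(dets, truth)
  perm <- sample(nrow(dets))
  m_p <- match_detections(dets[perm, ], truth)
  expect_equal(recall(m_p), recall(m))
  expect_equal(precision(m_p), precision(m))

  # adding a pure false positive cannot raise precision
  worse <- dplyr::bind_rows(dets, dets_tbl(500, 500))
  expect_lte(precision(match_detections(worse, truth)), precision(m))

  # matching one more fruit cannot lower recall
  better <- dplyr::bind_rows(dets, dets_tbl(truth$row[5], truth$col[5]))
  expect_gte(recall(match_detections(better, truth)), recall(m))
})

test_that("vertical partition is exact and half-open at the cuts", {
  img <- flat_image(300, 40, c(5, 5, 5))
  truth <- truth_tbl(row = c(50, 100, 150, 200, 299), col = 20, radius = 4,
                     stage = "immature")
  parts <- partition_parts(img, truth, c(100, 200))
  expect_named(parts, c("top", "middle", "bottom"))
  expect_equal(dim(parts$top$image)[1], 99)
  expect_equal(dim(parts$middle$image)[1], 100)
  expect_equal(dim(parts$bottom$image)[1], 101)
  # rows 100 and 200 sit exactly on the cuts: middle and bottom
  expect_equal(nrow(parts$top$truth), 1)
  expect_equal(nrow(parts$middle$truth), 2)
  expect_equal(nrow(parts$bottom$truth), 2)
  # counts always reconcile
  expect_equal(nrow(parts$top$truth) + nrow(parts$middle$truth) +
                 nrow(parts$bottom$truth), nrow(truth))
  # coordinates shifted into each crop's frame
  expect_equal(parts$middle$truth$row, c(1, 51))
  expect_error(partition_parts(img, truth, c(200, 100)), "cut_rows")
})

test_that("report accessors agree with each other", {
  truth <- truth_tbl(row = c(10, 30, 50), col = 10, radius = 4,
                     stage = c("young", "immature", "mature"))
  rep <- detection_report(dets_tbl(c(10, 30), c(10, 10)), truth)
  expect_equal(rep$recall, 2 / 3)
  expect_equal(rep$precision, 1)
  td <- tidy(rep)
  expect_equal(td$recall[td$stage == "all"], rep$recall)
  gl <- glance(rep)
  expect_equal(gl$n_matched, 2)
  expect_output(print(rep), "precision")
})
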