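#' X-means clustering of one-dimensional values
#'
#' K-means with automatic selection of the number of clusters: starting
#' from a single cluster, every cluster is repeatedly offered a 2-means
#' split, and a split is kept when the Bayesian information criterion of
#' the two-cluster model of that cluster's points exceeds the one-cluster
#' BIC; ties favor fewer clusters. After each round of accepted splits
#' all centers are refined by a global Lloyd pass; the procedure stops at
#' a local BIC optimum or at `kmax` clusters.
#'
#' The BIC uses the hard-assignment spherical-Gaussian likelihood with
#' per-cluster maximum-likelihood variances and mixing weights
#' `n_j / n` (free parameters `3k - 1` in one dimension). Per-cluster
#' variances make splits of genuinely multi-modal clusters attractive
#' while the mixing-entropy term keeps single Gaussians whole; all
#' variances are floored at 0.1% of the overall spread so a handful of
#' near-identical (e.g. quantized) values cannot produce an unbounded
#' likelihood gain. In one dimension every 2-partition is an order cut,
#' so each split considers two deterministic cut proposals — the exact
#' SSE-optimal 2-means cut (found by a prefix-sum scan) and the
#' largest-gap cut — scored by BIC, with both children required to hold
#' at least 10 points (outlier-peeling guard). The whole procedure is
#' therefore deterministic; `seed` is accepted for interface uniformity
#' with the stochastic stages.
#'
#' @param values Numeric vector (at least one value).
#' @param kmax Upper bound on the number of clusters.
#' @param seed Unused placeholder (the 1-D algorithm is deterministic).
#' @return An object of class `xmeans`: a list with `k`, `assignment`
#'   (integer vector along `values`), `centers` and `cluster_means`
#'   (identical in 1-D, sorted increasing), and `n`.
#' @examples
#' x <- c(rnorm(100, 0.2, 0.02), rnorm(100, 0.9, 0.02))
#' xmeans_1d(x, kmax = 10)$k  # 2
#' @export
xmeans_1d <- function(values, kmax = 20, seed = 1L) {
  values <- as.numeric(values)
  if (length(values) == 0) abort("`values` must contain at least one value.")
  if (anyNA(values)) abort("`values` must be finite.")
  if (kmax < 1) abort("`kmax` must be at least 1.")
  n <- length(values)
  # variance floor fixed once at the root data scale (0.1% of overall
  # spread): per-cluster MLE variances otherwise diverge on a handful
  # of near-identical (e.g. quantized) points, shattering tight
  # clusters into micro-fragments
  floor2 <- 1e-3 * mean((values - mean(values))^2)

  centers <- mean(values)
  repeat {
    centers <- lloyd_1d(values, centers)$centers
    assign <- nearest_center(values, centers)
    improved <- FALSE
    k_total <- length(centers)
    new_centers <- numeric(0)
    for (j in seq_along(centers)) {
      pts <- values[assign == j]
      split <- NULL
      if (length(pts) >= 2 && k_total < kmax) {
        split <- try_split_1d(pts, floor2)
      }
      if (is.null(split)) {
        new_centers <- c(new_centers, centers[j])
      } else {
        new_centers <- c(new_centers, split)
        k_total <- k_total + 1
        improved <- TRUE
      }
    }
    centers <- new_centers
    if (!improved || length(centers) >= kmax) break
  }

  centers <- lloyd_1d(values, centers)$centers
  centers <- sort(centers)
  assign <- nearest_center(values, centers)
  # drop empty clusters (possible after refinement of near-duplicate centers)
  used <- sort(unique(assign))
  centers <- centers[used]
  assign <- match(assign, used)
  structure(
    list(k = length(centers), assignment = assign, centers = centers,
         cluster_means = centers, n = n),
    class = "xmeans"
  )
}

#' @export
print.xmeans <- function(x, ...) {
  cat(sprintf("<xmeans: %d cluster%s over %d values>\n",
              x$k, if (x$k == 1) "" else "s", x$n))
  cat("  centers:", paste(signif(x$centers, 4), collapse = ", "), "\n")
  invisible(x)
}

nearest_center <- function(values, centers) {
  d <- outer(values, centers, function(v, c) (v - c)^2)
  max.col(-d, ties.method = "first")
}

# Lloyd iterations to convergence; empty clusters are dropped
lloyd_1d <- function(values, centers, max_iter = 100) {
  for (it in seq_len(max_iter)) {
    assign <- nearest_center(values, centers)
    new_centers <- vapply(seq_along(centers), function(j) {
      pts <- values[assign == j]
      if (length(pts) == 0) NA_real_ else mean(pts)
    }, double(1))
    new_centers <- new_centers[!is.na(new_centers)]
    if (length(new_centers) == length(centers) &&
        max(abs(new_centers - centers)) < 1e-12) {
      return(list(centers = new_centers, assignment = assign))
    }
    centers <- new_centers
  }
  list(centers = centers, assignment = nearest_center(values, centers))
}

# Spherical-Gaussian BIC (d = 1) of a hard-assigned K-cluster model with
# per-cluster MLE variances (each cluster its own sigma_j^2) and mixing
# weights n_j / n. Per-cluster variances make splits of genuinely
# multi-modal clusters attractive, while the mixing-entropy term keeps
# splits of single Gaussians unattractive; the pooled-variance variant
# rejects top-level splits of many-component mixtures outright.
# Free parameters: K means + K variances + (K - 1) weights.
bic_1d <- function(values, centers, floor2 = 1e-3 * mean((values - mean(values))^2)) {
  n <- length(values)
  K <- length(centers)
  if (n <= K) return(-Inf)
  assign <- nearest_center(values, centers)
  nj <- tabulate(assign, nbins = K)
  if (any(nj < 2)) return(-Inf)       # degenerate single-point cluster
  ll <- 0
  for (j in seq_len(K)) {
    sigma2 <- sum((values[assign == j] - centers[j])^2) / nj[j] + floor2
    if (sigma2 <= 0) return(Inf)      # all values identical
    ll <- ll + nj[j] * log(nj[j] / n) -
      nj[j] / 2 * log(2 * pi * sigma2) - nj[j] / 2
  }
  p <- 3 * K - 1
  ll - p / 2 * log(n)
}

# Exact optimal 2-means of one cluster's points (1-D: sort once, scan
# every cut with prefix sums); returns the two child centers when the
# two-cluster BIC strictly beats the one-cluster BIC, else NULL. The
# exact optimum is deterministic and never places a boundary worse than
# any Lloyd local optimum, which protects against spurious fragments.
try_split_1d <- function(pts, floor2 = 1e-3 * mean((pts - mean(pts))^2)) {
  if (min(pts) == max(pts)) return(NULL)
  s <- sort(pts)
  n <- length(s)
  if (n < 4) return(NULL)             # children need two points each
  cs <- cumsum(s)
  cs2 <- cumsum(s^2)
  # two deterministic cut proposals, each scored as the two-cluster
  # model of its own partition (MLE means and variances from prefix
  # sums): the exact SSE-optimal 2-means cut, and the largest-gap cut
  # (which never bisects a well-separated component)
  i <- seq_len(n - 1)
  sse_left <- cs2[i] - cs[i]^2 / i
  sse_right <- (cs2[n] - cs2[i]) - (cs[n] - cs[i])^2 / (n - i)
  cuts <- unique(c(which.min(sse_left + sse_right), which.max(diff(s))))
  # each child must carry enough points to estimate a variance and to
  # rule out outlier peeling: isolating a couple of stray tail points
  # shrinks the sibling's variance enough to pass the BIC test, and the
  # stray center then captures half of a genuine component during the
  # global refinement pass
  min_child <- min(10, max(2, n %/% 4))
  cuts <- cuts[cuts >= min_child & cuts <= n - min_child]
  if (length(cuts) == 0) return(NULL)
  bic_cut <- function(cut) {
    nl <- cut; nr <- n - cut
    ml <- cs[cut] / nl; mr <- (cs[n] - cs[cut]) / nr
    vl <- max(cs2[cut] / nl - ml^2, 0) + floor2
    vr <- max((cs2[n] - cs2[cut]) / nr - mr^2, 0) + floor2
    if (vl <= 0 || vr <= 0) return(Inf)   # children of a constant
    ll <- nl * log(nl / n) - nl / 2 * log(2 * pi * vl) - nl / 2 +
      nr * log(nr / n) - nr / 2 * log(2 * pi * vr) - nr / 2
    ll - 5 / 2 * log(n)
  }
  bic1 <- bic_1d(pts, mean(pts), floor2)
  scores <- vapply(cuts, bic_cut, double(1))
  best <- which.max(scores)
  if (scores[best] <= bic1) return(NULL)
  cut <- cuts[best]
  child <- c(cs[cut] / cut, (cs[n] - cs[cut]) / (n - cut))
  if (child[1] == child[2]) return(NULL)
  child
}
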