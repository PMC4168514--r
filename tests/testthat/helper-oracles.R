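# Independent oracles used by the tests. These deliberately use naive
# per-pixel loops / exhaustive enumeration so they share no code with the
# implementation they check.

# CIELAB from 8-bit sRGB via the closed-form sRGB -> XYZ (D65) -> Lab chain
oracle_lab <- function(rgb255) {
  lin <- vapply(rgb255 / 255, function(u) {
    if (u <= 0.04045) u / 12.92 else ((u + 0.055) / 1.055)^2.4
  }, double(1))
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  xyz <- as.numeric(M %*% lin)
  white <- c(0.95047, 1, 1.08883)
  f <- vapply(xyz / white, function(t) {
    if (t > (6 / 29)^3) t^(1 / 3) else t / (3 * (6 / 29)^2) + 4 / 29
  }, double(1))
  c(L = 116 * f[2] - 16, a = 500 * (f[1] - f[2]), b = 200 * (f[2] - f[3]))
}

# per-pixel loop over an image, calling the scalar feature path
oracle_feature_loop <- function(image) {
  d <- dim(image)
  planes <- array(NA_real_, dim = c(d[1], d[2], 15))
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      planes[i, j, ] <- as.numeric(pixel_features(image[i, j, ])[1, ])
    }
  }
  planes
}

# brute-force symmetric GLCM at offset (0, 1) over the full patch
oracle_glcm_asm <- function(gray) {
  counts <- matrix(0, 256, 256)
  for (i in seq_len(nrow(gray))) {
    for (j in seq_len(ncol(gray) - 1)) {
      a <- gray[i, j] + 1; b <- gray[i, j + 1] + 1
      counts[a, b] <- counts[a, b] + 1
      counts[b, a] <- counts[b, a] + 1
    }
  }
  p <- counts / sum(counts)
  sum(p^2)
}

# brute-force 8-connected labeling by repeated flood fill
oracle_label8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    H <- nrow(mask)
    while (length(queue) > 0) {
      q <- queue[1]; queue <- queue[-1]
      r <- (q - 1) %% H + 1; c <- (q - 1) %/% H + 1
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr < 1 || rr > H || cc < 1 || cc > ncol(mask)) next
        q2 <- (cc - 1) * H + rr
        if (mask[q2] && lab[q2] == 0) {
          lab[q2] <- nxt
          queue <- c(queue, q2)
        }
      }
    }
  }
  lab
}

# exhaustive maximum-cardinality, minimum-total-distance assignment of
# detections to fruits under the within-disk eligibility rule
oracle_assignment <- function(dets, truth) {
  nd <- nrow(dets); nf <- nrow(truth)
  if (nd == 0 || nf == 0) return(list(n = 0, cost = 0))
  dist <- outer(seq_len(nd), seq_len(nf), function(i, j) {
    sqrt((dets$row[i] - truth$row[j])^2 + (dets$col[i] - truth$col[j])^2)
  })
  elig <- dist <= matrix(truth$radius, nd, nf, byrow = TRUE)
  best <- list(n = 0, cost = Inf)
  recurse <- function(i, used_f, n, cost) {
    if (i > nd) {
      if (n > best$n || (n == best$n && cost < best$cost)) {
        best <<- list(n = n, cost = cost)
      }
      return()
    }
    recurse(i + 1, used_f, n, cost)          # leave detection i unmatched
    for (j in which(elig[i, ] & !used_f)) {
      used_f[j] <- TRUE
      recurse(i + 1, used_f, n + 1, cost + dist[i, j])
      used_f[j] <- FALSE
    }
  }
  recurse(1, rep(FALSE, nf), 0, 0)
  best
}

# exhaustive k-means via many restarts (oracle for within-cluster SSE)
oracle_kmeans_sse <- function(values, k, restarts = 200) {
  best <- Inf
  for (r in seq_len(restarts)) {
    centers <- sample(values, k)
    for (it in 1:50) {
      assign <- apply(outer(values, centers, function(v, c) (v - c)^2), 1,
                      which.min)
      newc <- vapply(seq_len(k), function(j) {
        pts <- values[assign == j]
        if (length(pts) == 0) centers[j] else mean(pts)
      }, double(1))
      if (max(abs(newc - centers)) < 1e-12) break
      centers <- newc
    }
    sse <- sum((values - centers[assign])^2)
    best <- min(best, sse)
  }
  best
}
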