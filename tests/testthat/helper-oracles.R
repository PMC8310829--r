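# Independent brute-force oracles. These deliberately use naive loops (or a
# different library) rather than the package's vectorized implementations.

# Point-in-polygon via pracma, with a tiny up-right nudge so boundary pixels
# resolve to the half-open (lower-left inclusive) convention.
oracle_pixels_inside <- function(contour, frame_shape) {
  xs <- rep(0:(frame_shape[2] - 1), each = frame_shape[1])
  ys <- rep(0:(frame_shape[1] - 1), times = frame_shape[2])
  inside <- pracma::inpolygon(xs + 1e-9, ys + 1e-9,
                              contour[, 1], contour[, 2])
  sum(inside)
}

# Symmetric normalized GLCM by explicit pair enumeration.
oracle_glcm <- function(levels, dr, dc, n_levels) {
  counts <- matrix(0, n_levels, n_levels)
  for (r in seq_len(nrow(levels))) {
    for (c in seq_len(ncol(levels))) {
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nrow(levels) || c2 < 1 || c2 > ncol(levels)) next
      a <- levels[r, c]; b <- levels[r2, c2]
      if (is.na(a) || is.na(b)) next
      counts[a, b] <- counts[a, b] + 1
      counts[b, a] <- counts[b, a] + 1
    }
  }
  counts
}

oracle_glcm_features <- function(P) {
  n <- nrow(P)
  f <- c(contrast = 0, dissimilarity = 0, inverse_difference = 0, asm = 0,
         correlation = 0, entropy = 0, cluster_shade = 0,
         cluster_prominence = 0)
  mu_i <- 0; mu_j <- 0
  for (i in 1:n) for (j in 1:n) { mu_i <- mu_i + i * P[i, j]; mu_j <- mu_j + j * P[i, j] }
  v_i <- 0; v_j <- 0
  for (i in 1:n) for (j in 1:n) {
    v_i <- v_i + (i - mu_i)^2 * P[i, j]; v_j <- v_j + (j - mu_j)^2 * P[i, j]
  }
  corr_num <- 0
  for (i in 1:n) for (j in 1:n) {
    p <- P[i, j]
    f["contrast"] <- f["contrast"] + (i - j)^2 * p
    f["dissimilarity"] <- f["dissimilarity"] + abs(i - j) * p
    f["inverse_difference"] <- f["inverse_difference"] + p / (1 + abs(i - j))
    f["asm"] <- f["asm"] + p^2
    if (p > 0) f["entropy"] <- f["entropy"] - p * log2(p)
    f["cluster_shade"] <- f["cluster_shade"] + (i + j - mu_i - mu_j)^3 * p
    f["cluster_prominence"] <- f["cluster_prominence"] + (i + j - mu_i - mu_j)^4 * p
    corr_num <- corr_num + (i - mu_i) * (j - mu_j) * p
  }
  f["correlation"] <- if (v_i > 0 && v_j > 0) corr_num / sqrt(v_i * v_j) else 1
  f
}

# Runs along one direction by explicit walking; counts[level, length].
oracle_glrlm <- function(levels, dr, dc, n_levels) {
  nr <- nrow(levels); nc <- ncol(levels)
  counts <- matrix(0, n_levels, max(nr, nc))
  visited <- matrix(FALSE, nr, nc)
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    pr <- r0 - dr; pc <- c0 - dc
    if (pr >= 1 && pr <= nr && pc >= 1 && pc <= nc) next  # not a line start
    r <- r0; c <- c0
    run_val <- NA; run_len <- 0
    while (r >= 1 && r <= nr && c >= 1 && c <= nc) {
      v <- levels[r, c]
      if (!is.na(v) && !is.na(run_val) && v == run_val) {
        run_len <- run_len + 1
      } else {
        if (!is.na(run_val)) counts[run_val, run_len] <- counts[run_val, run_len] + 1
        run_val <- v; run_len <- if (is.na(v)) 0 else 1
      }
      r <- r + dr; c <- c + dc
    }
    if (!is.na(run_val) && run_len > 0) {
      counts[run_val, run_len] <- counts[run_val, run_len] + 1
    }
  }
  counts
}

oracle_glrlm_features <- function(R, n_pixels) {
  S <- sum(R)
  f <- c(sre = 0, lre = 0, gln = 0, rln = 0, rp = 0, lglre = 0, hglre = 0)
  for (i in seq_len(nrow(R))) for (j in seq_len(ncol(R))) {
    f["sre"] <- f["sre"] + R[i, j] / j^2
    f["lre"] <- f["lre"] + R[i, j] * j^2
    f["lglre"] <- f["lglre"] + R[i, j] / i^2
    f["hglre"] <- f["hglre"] + R[i, j] * i^2
  }
  f["gln"] <- sum(rowSums(R)^2)
  f["rln"] <- sum(colSums(R)^2)
  f[c("sre", "lre", "gln", "rln", "lglre", "hglre")] <-
    f[c("sre", "lre", "gln", "rln", "lglre", "hglre")] / S
  f["rp"] <- S / n_pixels
  f
}

# 8-connected zones by BFS flood fill; returns data.frame(level, size).
oracle_glszm_zones <- function(levels) {
  nr <- nrow(levels); nc <- ncol(levels)
  seen <- matrix(FALSE, nr, nc)
  out <- NULL
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (seen[r0, c0] || is.na(levels[r0, c0])) next
    lv <- levels[r0, c0]
    queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE; size <- 0
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]; size <- size + 1
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r <- p[1] + dr; c <- p[2] + dc
        if (r < 1 || r > nr || c < 1 || c > nc) next
        if (seen[r, c] || is.na(levels[r, c]) || levels[r, c] != lv) next
        seen[r, c] <- TRUE
        queue[[length(queue) + 1]] <- c(r, c)
      }
    }
    out <- rbind(out, data.frame(level = lv, size = size))
  }
  out
}

oracle_glszm_features <- function(zones, n_pixels) {
  S <- nrow(zones)
  ri <- table(zones$level)
  rj <- table(zones$size)
  c(glszm_sze = sum(1 / zones$size^2) / S,
    glszm_lze = sum(zones$size^2) / S,
    glszm_gln = sum(ri^2) / S,
    glszm_zsn = sum(rj^2) / S,
    glszm_zp = S / n_pixels)
}

# Andrew's monotone-chain convex hull area (independent of grDevices::chull).
oracle_hull_area <- function(pts) {
  pts <- unique(pts[order(pts[, 1], pts[, 2]), , drop = FALSE])
  cross <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  build <- function(seq_idx) {
    h <- list()
    for (i in seq_idx) {
      p <- pts[i, ]
      while (length(h) >= 2 &&
             cross(h[[length(h) - 1]], h[[length(h)]], p) <= 0) {
        h[[length(h)]] <- NULL
      }
      h[[length(h) + 1]] <- p
    }
    h
  }
  lower <- build(seq_len(nrow(pts)))
  upper <- build(rev(seq_len(nrow(pts))))
  hull <- do.call(rbind, c(lower[-length(lower)], upper[-length(upper)]))
  x <- hull[, 1]; y <- hull[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Random discretized ROI on a 6 x 6 grid: levels 1..4 inside a random mask.
random_levels_roi <- function(seed, n = 6, n_levels = 4, p_mask = 0.75) {
  withr::with_seed(seed, {
    lv <- matrix(sample(seq_len(n_levels), n * n, replace = TRUE), n, n)
    mask <- matrix(runif(n * n) < p_mask, n, n)
    if (sum(mask) < 4) mask[sample(n * n, 4)] <- TRUE
    lv[!mask] <- NA
    lv
  })
}

# Closed circle contour helper.
circle_contour <- function(cx, cy, r, n = 96) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}
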