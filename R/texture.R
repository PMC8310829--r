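# Grey-level co-occurrence, run-length, and size-zone texture families,
# computed on discretized levels within a mask. Aggregation follows the
# angle-averaged convention: one matrix per direction, features averaged
# over directions.

# Direction offsets (dr, dc) for the four standard 2D angles at distance d:
# 0 deg, 45 deg, 90 deg, 135 deg.
.texture_offsets <- function(d = 1L) {
  list(c(0L, d), c(-d, d), c(-d, 0L), c(-d, -d))
}

# Co-occurrence counts for one offset; symmetric by construction.
.glcm_matrix <- function(levels, offset, n_levels) {
  nr <- nrow(levels); nc <- ncol(levels)
  dr <- offset[1]; dc <- offset[2]
  r1 <- max(1, 1 - dr):min(nr, nr - dr)
  c1 <- max(1, 1 - dc):min(nc, nc - dc)
  a <- levels[r1, c1, drop = FALSE]
  b <- levels[r1 + dr, c1 + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NULL)
  tab <- matrix(tabulate((a[ok] - 1L) * n_levels + b[ok], n_levels^2),
                n_levels, n_levels)
  t(tab) + tab
}

.glcm_feature_set <- function(P) {
  n <- nrow(P)
  i <- matrix(seq_len(n), n, n)
  j <- t(i)
  mu_i <- sum(i * P); mu_j <- sum(j * P)
  sd_i <- sqrt(sum((i - mu_i)^2 * P)); sd_j <- sqrt(sum((j - mu_j)^2 * P))
  corr <- if (sd_i > 0 && sd_j > 0) {
    sum((i - mu_i) * (j - mu_j) * P) / (sd_i * sd_j)
  } else 1
  pnz <- P[P > 0]
  c(
    contrast = sum((i - j)^2 * P),
    dissimilarity = sum(abs(i - j) * P),
    inverse_difference = sum(P / (1 + abs(i - j))),
    asm = sum(P^2),
    correlation = corr,
    entropy = -sum(pnz * log2(pnz)),
    cluster_shade = sum((i + j - mu_i - mu_j)^3 * P),
    cluster_prominence = sum((i + j - mu_i - mu_j)^4 * P)
  )
}

#' Grey-level co-occurrence (GLCM) features
#'
#' For each distance, builds symmetric co-occurrence matrices over
#' within-mask pixel pairs along the four 2D directions, normalizes each,
#' and averages the features over directions.
#'
#' @param levels integer level matrix from [discretize()] (`NA` outside ROI).
#' @param distances integer pixel offsets; default `c(1, 2, 4)`.
#' @return named numeric vector, names `glcm_d<d>_<feature>`.
#' @export
glcm_features <- function(levels, distances = c(1L, 2L, 4L)) {
  n_levels <- max(levels, na.rm = TRUE)
  out <- numeric(0)
  for (d in distances) {
    mats <- lapply(.texture_offsets(as.integer(d)), .glcm_matrix,
                   levels = levels, n_levels = n_levels)
    mats <- mats[!vapply(mats, is.null, logical(1))]
    if (!length(mats)) {
      warn(sprintf("No within-mask pixel pairs at distance %d; features omitted.", d))
      next
    }
    feats <- vapply(mats, function(m) .glcm_feature_set(m / sum(m)),
                    numeric(8))
    avg <- rowMeans(feats)
    names(avg) <- sprintf("glcm_d%d_%s", d, names(avg))
    out <- c(out, avg)
  }
  out
}

# Maximal same-level runs along one direction; returns a matrix of counts
# indexed [level, run length]. Runs break at mask borders (NA). Run content
# is direction-symmetric, so each of the four angles is scanned once.
.glrlm_matrix <- function(levels, offset, n_levels) {
  nr <- nrow(levels); nc <- ncol(levels)
  dr <- offset[1]; dc <- offset[2]
  lines <- if (dr == 0L) {
    split(as.vector(t(levels)), rep(seq_len(nr), each = nc))
  } else if (dc == 0L) {
    split(as.vector(levels), rep(seq_len(nc), each = nr))
  } else if (dr * dc > 0 || (dr == -1L && dc == -1L)) {
    # 135-degree family: constant row - col; column-major order walks (1, 1)
    split(as.vector(levels), as.vector(row(levels) - col(levels)))
  } else {
    # 45-degree family: constant row + col; column-major order walks (-1, 1)
    split(as.vector(levels), as.vector(row(levels) + col(levels)))
  }
  max_run <- max(nr, nc)
  idx <- unlist(lapply(lines, function(ln) {
    rl <- rle(ln)
    keep <- !is.na(rl$values)
    (rl$lengths[keep] - 1L) * n_levels + rl$values[keep]
  }), use.names = FALSE)
  matrix(tabulate(idx, n_levels * max_run), n_levels, max_run)
}

.glrlm_feature_set <- function(R, n_pixels) {
  nr_runs <- sum(R)
  jj <- matrix(seq_len(ncol(R)), nrow(R), ncol(R), byrow = TRUE)
  ii <- matrix(seq_len(nrow(R)), nrow(R), ncol(R))
  rj <- colSums(R)    # runs per length
  ri <- rowSums(R)    # runs per level
  c(
    sre = sum(R / jj^2) / nr_runs,
    lre = sum(R * jj^2) / nr_runs,
    gln = sum(ri^2) / nr_runs,
    rln = sum(rj^2) / nr_runs,
    rp = nr_runs / n_pixels,
    lglre = sum(R / ii^2) / nr_runs,
    hglre = sum(R * ii^2) / nr_runs
  )
}

#' Grey-level run-length (GLRLM) features
#'
#' Run-length matrices along the four 2D directions, features averaged over
#' directions. Runs are maximal same-level segments within the mask.
#'
#' @inheritParams glcm_features
#' @return named numeric vector, names `glrlm_<feature>`.
#' @export
glrlm_features <- function(levels) {
  n_levels <- max(levels, na.rm = TRUE)
  n_pixels <- sum(!is.na(levels))
  feats <- vapply(.texture_offsets(1L), function(off) {
    R <- .glrlm_matrix(levels, off, n_levels)
    .glrlm_feature_set(R, n_pixels)
  }, numeric(7))
  avg <- rowMeans(feats)
  names(avg) <- paste0("glrlm_", names(avg))
  avg
}

#' Grey-level size-zone (GLSZM) features
#'
#' Zones are 8-connected components of equal level within the mask. The
#' size-zone matrix needs no direction, so no averaging is involved.
#'
#' @inheritParams glcm_features
#' @return named numeric vector, names `glszm_<feature>`.
#' @export
glszm_features <- function(levels) {
  n_levels <- max(levels, na.rm = TRUE)
  n_pixels <- sum(!is.na(levels))
  zones <- glszm_zones(levels)
  S <- sum(zones$n)
  sz <- zones$size
  ri <- tapply(rep(1, nrow(zones)), factor(zones$level, seq_len(n_levels)), sum)
  ri[is.na(ri)] <- 0
  rj <- tapply(rep(1, nrow(zones)), factor(zones$size, seq_len(max(sz))), sum)
  rj[is.na(rj)] <- 0
  c(
    glszm_sze = sum(1 / sz^2) / S,
    glszm_lze = sum(sz^2) / S,
    glszm_gln = sum(ri^2) / S,
    glszm_zsn = sum(rj^2) / S,
    glszm_zp = S / n_pixels
  )
}

#' Enumerate grey-level zones
#'
#' @param levels integer level matrix (`NA` outside ROI).
#' @return tibble with one row per 8-connected equal-level zone: `level`,
#'   `size`, `n` (= 1; kept for aggregation convenience).
#' @export
glszm_zones <- function(levels) {
  lv <- sort(unique(levels[!is.na(levels)]))
  res <- purrr::map_dfr(lv, function(l) {
    lab <- label_components8(!is.na(levels) & levels == l)
    if (!any(lab > 0)) return(NULL)
    sizes <- tabulate(lab[lab > 0])
    tibble::tibble(level = l, size = sizes, n = 1L)
  })
  res
}
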