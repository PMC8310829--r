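# First-order and morphometric radiomic features.

#' Grey-level discretization settings
#'
#' Fixed-bin-number discretization over the within-ROI intensity range, the
#' common IBSI-compliant choice for texture matrices.
#'
#' @param n_bins number of grey levels (>= 2); default 64.
#' @param range_mode `"roi_min_max"` (rescale the ROI's own range) or
#'   `"fixed"` with explicit `range`.
#' @param range length-2 numeric used when `range_mode = "fixed"`.
#' @return a `discretization_config` list.
#' @export
discretization_config <- function(n_bins = 64, range_mode = c("roi_min_max", "fixed"),
                                  range = c(0, 255)) {
  if (n_bins < 2) abort("`n_bins` must be >= 2.")
  structure(list(n_bins = as.integer(n_bins),
                 range_mode = match.arg(range_mode), range = range),
            class = "discretization_config")
}

#' Discretize ROI intensities to integer grey levels
#'
#' Maps intensity `I` to level `1 + floor(n_bins * (I - min) / (max - min))`,
#' clamped to `n_bins` at `I = max`. A constant ROI maps wholly to level 1.
#'
#' @param frame an [om_frame()] (or bare matrix).
#' @param mask logical matrix congruent with the frame.
#' @param cfg a [discretization_config()].
#' @return integer matrix with levels `1..n_bins` inside the mask and `NA`
#'   outside.
#' @export
discretize <- function(frame, mask, cfg = discretization_config()) {
  px <- if (inherits(frame, "om_frame")) frame$pixels else frame
  if (!any(mask)) abort("`mask` is empty.")
  vals <- px[mask]
  rng <- if (cfg$range_mode == "fixed") cfg$range else range(vals)
  levels <- matrix(NA_integer_, nrow(px), ncol(px))
  if (rng[2] <= rng[1]) {
    levels[mask] <- 1L
    return(levels)
  }
  lv <- 1L + as.integer(floor(cfg$n_bins * (vals - rng[1]) / (rng[2] - rng[1])))
  levels[mask] <- pmin(pmax(lv, 1L), cfg$n_bins)
  levels
}

#' First-order intensity statistics within a mask
#'
#' @param frame an [om_frame()] or matrix.
#' @param mask logical matrix.
#' @param n_bins histogram bins used for entropy/uniformity (shares the
#'   texture discretization default).
#' @return named numeric vector of first-order features.
#' @export
firstorder_features <- function(frame, mask, n_bins = 64) {
  px <- if (inherits(frame, "om_frame")) frame$pixels else frame
  v <- px[mask]
  n <- length(v)
  mu <- mean(v)
  qs <- unname(quantile(v, c(0.1, 0.25, 0.75, 0.9), type = 7))
  lv <- discretize(px, mask, discretization_config(n_bins))[mask]
  p <- tabulate(lv, n_bins) / n
  p <- p[p > 0]
  c(
    fo_mean = mu,
    fo_variance = mean((v - mu)^2),
    fo_skewness = if (sd(v) > 0) mean((v - mu)^3) / mean((v - mu)^2)^1.5 else 0,
    fo_kurtosis = if (sd(v) > 0) mean((v - mu)^4) / mean((v - mu)^2)^2 else 0,
    fo_energy = sum(v^2),
    fo_entropy = -sum(p * log2(p)),
    fo_p10 = qs[1],
    fo_p90 = qs[4],
    fo_iqr = qs[3] - qs[2],
    fo_range = max(v) - min(v),
    fo_mad = mean(abs(v - mu)),
    fo_rms = sqrt(mean(v^2)),
    fo_uniformity = sum(p^2)
  )
}

# Marching-squares boundary length of a binary mask, in pixel units. The
# padded mask is lightly smoothed first so the 0.5-isoline sits at the
# sub-pixel boundary instead of on the staircase (which overestimates a
# disk's perimeter by ~5%).
.mask_perimeter <- function(mask) {
  pad <- matrix(0, nrow(mask) + 4, ncol(mask) + 4)
  pad[3:(nrow(mask) + 2), 3:(ncol(mask) + 2)] <- as.numeric(mask)
  pad <- EBImage::gblur(pad, sigma = 0.9)
  cl <- grDevices::contourLines(x = seq_len(nrow(pad)), y = seq_len(ncol(pad)),
                                z = pad, levels = 0.5)
  sum(vapply(cl, function(seg) {
    sum(sqrt(diff(seg$x)^2 + diff(seg$y)^2)) +
      sqrt((seg$x[1] - tail(seg$x, 1))^2 + (seg$y[1] - tail(seg$y, 1))^2)
  }, numeric(1)))
}

#' Morphometric (shape) features of a mask
#'
#' Area, marching-squares perimeter, equivalent diameter, ellipse axes from
#' second moments, eccentricity, circularity `4*pi*A/P^2`, solidity against
#' the convex hull, and the maximum Feret diameter. Lengths are in mm using
#' the frame's pixel spacing (isotropic spacing assumed for the mixed-unit
#' features).
#'
#' @param mask logical matrix.
#' @param spacing length-2 (row, col) mm/pixel.
#' @return named numeric vector of shape features.
#' @export
shape_features <- function(mask, spacing = c(1, 1)) {
  spacing <- rep_len(spacing, 2)
  s <- sqrt(prod(spacing))              # isotropic length scale
  idx <- which(mask)
  nr <- nrow(mask)
  yy <- (idx - 1) %% nr                 # 0-based row (y)
  xx <- (idx - 1) %/% nr                # 0-based col (x)
  n <- length(idx)
  area <- n * prod(spacing)
  per <- .mask_perimeter(mask) * s
  # central second moments of pixel centers (+1/12 per-pixel square term)
  cx <- mean(xx); cy <- mean(yy)
  mxx <- mean((xx - cx)^2) + 1 / 12
  myy <- mean((yy - cy)^2) + 1 / 12
  mxy <- mean((xx - cx) * (yy - cy))
  tr <- mxx + myy
  dt <- sqrt(max((mxx - myy)^2 + 4 * mxy^2, 0))
  l1 <- (tr + dt) / 2; l2 <- max((tr - dt) / 2, 1e-12)
  major <- 4 * sqrt(l1) * s
  minor <- 4 * sqrt(l2) * s
  # convex hull of the pixel corner cloud (so a filled square has solidity 1)
  corners <- cbind(
    x = c(xx - 0.5, xx + 0.5, xx - 0.5, xx + 0.5),
    y = c(yy - 0.5, yy - 0.5, yy + 0.5, yy + 0.5)
  )
  h <- grDevices::chull(corners)
  hull <- corners[h, , drop = FALSE]
  hull_area <- polygon_area(hull) * prod(spacing)
  dmax <- 0
  hv <- hull
  if (nrow(hv) >= 2) {
    dmax <- sqrt(max(outer(hv[, 1], hv[, 1], "-")^2 +
                       outer(hv[, 2], hv[, 2], "-")^2)) * s
  }
  c(
    shape_area_mm2 = area,
    shape_perimeter_mm = per,
    shape_equiv_diameter_mm = 2 * sqrt(area / pi),
    shape_major_axis_mm = major,
    shape_minor_axis_mm = minor,
    shape_eccentricity = sqrt(max(1 - l2 / l1, 0)),
    shape_circularity = 4 * pi * area / per^2,
    shape_solidity = min(area / hull_area, 1),
    shape_feret_max_mm = dmax
  )
}
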