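# Contour rasterization and the random contour manipulations that emulate
# segmentation by different operators.

#' Rasterize a closed contour to a binary mask
#'
#' A pixel belongs to the mask iff its center lies inside the polygon under
#' the even-odd rule. Crossings are counted with half-open edge intervals so
#' that pixels on shared boundaries are assigned exactly once (an axis-aligned
#' box `[a, b] x [c, d]` fills the half-open pixel range `[a, b) x [c, d)`).
#' If rasterization yields several 8-connected components, only the largest
#' is kept.
#'
#' @param contour numeric matrix with columns `x`, `y` (0-based pixel
#'   coordinates, x = column, y = row).
#' @param frame_shape integer (rows, cols) of the target frame.
#' @param min_pixels minimum foreground size; smaller masks raise an error.
#' @return logical matrix of dimension `frame_shape`, class `om_mask`.
#' @export
rasterize_contour <- function(contour, frame_shape, min_pixels = 50) {
  contour <- as.matrix(contour)[, 1:2, drop = FALSE]
  nr <- frame_shape[1]; nc <- frame_shape[2]
  x1 <- contour[, 1]; y1 <- contour[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  keep <- y1 != y2                      # horizontal edges never cross a row
  x1 <- x1[keep]; x2 <- x2[keep]; y1 <- y1[keep]; y2 <- y2[keep]
  mask <- matrix(FALSE, nr, nc)
  if (length(x1)) {
    xs <- 0:(nc - 1)
    for (yc in 0:(nr - 1)) {
      cross <- (y1 <= yc & yc < y2) | (y2 <= yc & yc < y1)
      if (!any(cross)) next
      xi <- x1[cross] + (yc - y1[cross]) * (x2[cross] - x1[cross]) /
        (y2[cross] - y1[cross])
      # crossing number to the right of each pixel center
      cnt <- colSums(outer(xi, xs, ">"))
      mask[yc + 1, ] <- cnt %% 2 == 1
    }
  }
  if (any(mask)) mask <- largest_component8(mask)
  if (sum(mask) < min_pixels) {
    abort(sprintf(
      "Contour rasterizes to %d pixels; at least %d are required for feature extraction.",
      sum(mask), min_pixels
    ))
  }
  structure(mask, class = c("om_mask", "matrix", "array"))
}

#' Jaccard overlap of two masks
#'
#' @param a,b logical matrices of equal dimension.
#' @return intersection-over-union in `[0, 1]`.
#' @export
mask_jaccard <- function(a, b) {
  sum(a & b) / sum(a | b)
}

#' Perturbation settings for contour manipulation
#'
#' @param n_variants number of perturbed contours to draw (>= 1).
#' @param amplitude_frac peak radial displacement as a fraction of the
#'   contour's equivalent radius, in `[0, 0.15]`. The default 0.05 keeps the
#'   variants within the spread of careful manual tracings by different
#'   operators.
#' @param smoothness number of low-order Fourier harmonics in the random
#'   radial displacement field; small values give smooth, operator-like
#'   deviations.
#' @param seed optional integer seed; the same seed reproduces the same
#'   variant list.
#' @return a `perturbation_config` list.
#' @export
perturbation_config <- function(n_variants = 20, amplitude_frac = 0.05,
                                smoothness = 6, seed = NULL) {
  if (n_variants < 1) abort("`n_variants` must be >= 1.")
  if (amplitude_frac < 0 || amplitude_frac > 0.15) {
    abort("`amplitude_frac` must lie in [0, 0.15].")
  }
  if (smoothness < 1) abort("`smoothness` must be >= 1.")
  structure(list(n_variants = as.integer(n_variants),
                 amplitude_frac = amplitude_frac,
                 smoothness = as.integer(smoothness), seed = seed),
            class = "perturbation_config")
}

# Low-order harmonic displacement field evaluated at vertex angles theta.
.harmonic_field <- function(theta, smoothness) {
  f <- numeric(length(theta))
  for (h in seq_len(smoothness)) {
    f <- f + rnorm(1) * cos(h * theta) + rnorm(1) * sin(h * theta)
  }
  f
}

#' Randomly manipulate a contour
#'
#' Emulates re-segmentation by different operators: each variant displaces
#' the contour radially from its centroid by a smooth random field (a sum of
#' the first `smoothness` Fourier harmonics in vertex angle, with random
#' amplitudes and phases), scaled so the peak displacement does not exceed
#' `amplitude_frac` times the contour's equivalent radius. Variants that
#' would leave the frame are clipped to its bounds with a warning.
#'
#' @param contour numeric matrix with columns `x`, `y`.
#' @param cfg a [perturbation_config()].
#' @param frame_shape optional (rows, cols) used to clip variants in-bounds.
#' @return list of `cfg$n_variants` contour matrices.
#' @export
perturb_contour <- function(contour, cfg = perturbation_config(),
                            frame_shape = NULL) {
  contour <- as.matrix(contour)[, 1:2, drop = FALSE]
  ctr <- polygon_centroid(contour)
  dx <- contour[, 1] - ctr[1]; dy <- contour[, 2] - ctr[2]
  r <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)
  r_eq <- sqrt(polygon_area(contour) / pi)
  draw <- function() {
    lapply(seq_len(cfg$n_variants), function(v) {
      if (cfg$amplitude_frac == 0) return(contour)
      f <- .harmonic_field(theta, cfg$smoothness)
      peak <- max(abs(f))
      if (peak > 0) {
        # utilization in (0.5, 1]: variants differ in magnitude, never exceed
        # the configured peak displacement
        f <- f / peak * (cfg$amplitude_frac * r_eq * runif(1, 0.5, 1))
      }
      r2 <- pmax(r + f, 0.05 * r_eq)
      out <- cbind(x = ctr[1] + r2 * cos(theta), y = ctr[2] + r2 * sin(theta))
      if (!is.null(frame_shape)) {
        clip_x <- pmin(pmax(out[, 1], 0), frame_shape[2] - 1)
        clip_y <- pmin(pmax(out[, 2], 0), frame_shape[1] - 1)
        if (any(clip_x != out[, 1] | clip_y != out[, 2])) {
          warn("Perturbed contour left the frame; clipped to bounds.")
          out <- cbind(x = clip_x, y = clip_y)
        }
      }
      out
    })
  }
  if (!is.null(cfg$seed)) withr::with_seed(cfg$seed, draw()) else draw()
}

#' Export a mask as an 8-bit PNG
#'
#' @param mask logical matrix.
#' @param path output path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask)), path)
  invisible(path)
}
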