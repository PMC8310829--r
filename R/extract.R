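# Full feature extraction for one (frame, contour) pair and across
# perturbed contour variants.

# Crop a level/pixel matrix pair to the mask bounding box (texture features
# only see within-mask pixels, so cropping is exact and much faster).
.crop_to_mask <- function(mat, mask) {
  rr <- range(which(rowSums(mask) > 0))
  cc <- range(which(colSums(mask) > 0))
  list(mat = mat[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE],
       mask = mask[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE])
}

# Otsu threshold of intensities within a mask (256-bin histogram).
.otsu_threshold <- function(vals) {
  rng <- range(vals)
  if (diff(rng) <= 0) return(rng[1])
  img <- matrix((vals - rng[1]) / diff(rng), nrow = 1)
  EBImage::otsu(EBImage::Image(img), range = c(0, 1)) * diff(rng) + rng[1]
}

# Intensity + texture fragment on one mask, with an optional name prefix.
.intensity_texture_fragment <- function(pixels, mask, disc_cfg, distances,
                                        prefix = "") {
  cr <- .crop_to_mask(pixels, mask)
  levels <- discretize(cr$mat, cr$mask, disc_cfg)
  out <- c(
    firstorder_features(cr$mat, cr$mask, n_bins = disc_cfg$n_bins),
    glcm_features(levels, distances = distances),
    glrlm_features(levels),
    glszm_features(levels)
  )
  if (nzchar(prefix)) names(out) <- paste0(prefix, names(out))
  out
}

#' Extract the full radiomic feature vector for one mask
#'
#' Concatenates first-order statistics, morphometry, and the GLCM/GLRLM/GLSZM
#' texture families. The candidate catalogue is identical across mass types;
#' panels diverge only after stability selection. For mixed masses the
#' intensity and texture families are additionally computed on the solid
#' subregion (pixels above the Otsu threshold within the contour) and
#' name-spaced with `solidsub_`.
#'
#' @param frame an [om_frame()].
#' @param mask logical mask congruent with the frame (from
#'   [rasterize_contour()]).
#' @param mass_type `"solid"`, `"cystic"` or `"mixed"`.
#' @param disc_cfg a [discretization_config()].
#' @param distances GLCM pixel distances.
#' @return named numeric vector; every catalogued feature present and finite.
#' @export
extract_features <- function(frame, mask, mass_type = "solid",
                             disc_cfg = discretization_config(),
                             distances = c(1L, 2L, 4L)) {
  match_mass_type(mass_type)
  out <- c(
    .intensity_texture_fragment(frame$pixels, mask, disc_cfg, distances),
    shape_features(mask, frame$spacing)
  )
  if (mass_type == "mixed") {
    vals <- frame$pixels[mask]
    thr <- .otsu_threshold(vals)
    sub <- mask & frame$pixels > thr
    sub <- if (any(sub)) largest_component8(sub) else sub
    if (sum(sub) >= 10) {
      out <- c(out, .intensity_texture_fragment(frame$pixels, sub, disc_cfg,
                                                distances,
                                                prefix = "solidsub_"))
    } else {
      # degenerate solid subregion: fall back to whole-mask values so the
      # catalogue stays complete and finite
      fb <- .intensity_texture_fragment(frame$pixels, mask, disc_cfg,
                                        distances, prefix = "solidsub_")
      out <- c(out, fb)
    }
  }
  if (any(!is.finite(out))) {
    bad <- names(out)[!is.finite(out)]
    abort(sprintf("Non-finite feature value(s): %s",
                  paste(bad, collapse = ", ")))
  }
  out
}

#' Extract features across random contour manipulations
#'
#' Rasterizes the manual contour, draws `cfg$n_variants` perturbed contours,
#' and extracts the full feature vector for each variant (variant 0 is the
#' unperturbed contour).
#'
#' @inheritParams extract_features
#' @param contour manual contour matrix (columns `x`, `y`).
#' @param cfg a [perturbation_config()].
#' @param include_original include the unperturbed contour as variant 0.
#' @return tibble, one row per variant: `case_id`, `variant`, then one column
#'   per feature.
#' @export
extract_case_features <- function(frame, contour, mass_type,
                                  cfg = perturbation_config(),
                                  disc_cfg = discretization_config(),
                                  distances = c(1L, 2L, 4L),
                                  include_original = TRUE) {
  shape <- dim(frame$pixels)
  variants <- perturb_contour(contour, cfg, frame_shape = shape)
  polys <- if (include_original) c(list(contour), variants) else variants
  ids <- if (include_original) seq_along(polys) - 1L else seq_along(polys)
  rows <- purrr::map2(polys, ids, function(poly, v) {
    mask <- rasterize_contour(poly, shape)
    fv <- extract_features(frame, mask, mass_type, disc_cfg, distances)
    tibble::as_tibble_row(c(list(case_id = frame$case_id, variant = v),
                            as.list(fv)))
  })
  dplyr::bind_rows(rows)
}

#' Aggregate per-variant features to one row per case
#'
#' The per-case representation used for model fitting and prediction is the
#' median of each feature across the contour variants, which damps the
#' residual dependence on any one manual tracing.
#'
#' @param feature_df tibble from [extract_case_features()] (possibly several
#'   cases row-bound).
#' @return tibble with one row per `case_id`.
#' @export
aggregate_variants <- function(feature_df) {
  feature_df |>
    dplyr::select(-dplyr::any_of("variant")) |>
    dplyr::group_by(.data$case_id) |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric), median),
                     .groups = "drop")
}
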