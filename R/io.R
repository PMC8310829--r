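# Imaging and tabular input/output: frames (DICOM/PNG), contours (CSV),
# cohort manifests (CSV).

#' Construct an ultrasound frame object
#'
#' A frame is one 2D grayscale intensity matrix with physical pixel spacing.
#' Pixel coordinates used throughout the package are 0-based and
#' pixel-centered, with `x` indexing columns and `y` indexing rows.
#'
#' @param pixels numeric matrix of finite non-negative intensities, at least
#'   2 x 2.
#' @param spacing length-2 numeric, (row, column) spacing in mm/pixel.
#' @param case_id identifier string.
#' @return an object of class `om_frame`.
#' @export
om_frame <- function(pixels, spacing = c(1, 1), case_id = "case") {
  if (!is.matrix(pixels) || nrow(pixels) < 2 || ncol(pixels) < 2) {
    abort("`pixels` must be a matrix of at least 2 x 2.")
  }
  if (!all(is.finite(pixels)) || any(pixels < 0)) {
    abort("Frame intensities must be finite and non-negative.")
  }
  spacing <- rep_len(as.numeric(spacing), 2)
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be positive and finite.")
  }
  structure(
    list(pixels = pixels, spacing = spacing, case_id = as.character(case_id)),
    class = "om_frame"
  )
}

#' @export
print.om_frame <- function(x, ...) {
  cat(sprintf(
    "<om_frame> %s: %d x %d px, %.3g x %.3g mm/px, intensity [%.3g, %.3g]\n",
    x$case_id, nrow(x$pixels), ncol(x$pixels), x$spacing[1], x$spacing[2],
    min(x$pixels), max(x$pixels)
  ))
  invisible(x)
}

#' Construct a mass annotation
#'
#' The examiner's input for one mass: its echotexture class, the manual
#' closed contour, and whether a posterior acoustic shadow is present.
#'
#' @param mass_type one of `"solid"`, `"cystic"`, `"mixed"`.
#' @param contour numeric matrix with columns `x`, `y` (>= 3 vertices) of a
#'   simple closed polygon in pixel coordinates; the closing edge from last
#'   to first vertex is implicit.
#' @param shadow_present logical flag.
#' @return an object of class `om_annotation`.
#' @export
om_annotation <- function(mass_type, contour, shadow_present = FALSE) {
  match_mass_type(mass_type)
  contour <- as.matrix(contour)[, 1:2, drop = FALSE]
  colnames(contour) <- c("x", "y")
  if (nrow(contour) < 3 || !all(is.finite(contour))) {
    abort("`contour` needs at least 3 finite (x, y) vertices.")
  }
  structure(
    list(mass_type = mass_type, contour = contour,
         shadow_present = isTRUE(shadow_present)),
    class = "om_annotation"
  )
}

#' Construct a clinical record
#'
#' @param ca125 serum CA-125 in U/mL, finite and non-negative.
#' @param menopausal `"pre"` or `"post"`.
#' @return an object of class `om_clinical`.
#' @export
om_clinical <- function(ca125, menopausal) {
  if (!is.finite(ca125) || ca125 < 0) {
    abort("`ca125` must be finite and non-negative (U/mL).")
  }
  match_menopausal(menopausal)
  structure(list(ca125 = as.numeric(ca125), menopausal = menopausal),
            class = "om_clinical")
}

# BT.601 luminance weights for RGB-to-grayscale conversion.
.bt601 <- c(0.299, 0.587, 0.114)

#' Read an image frame from DICOM or PNG
#'
#' RGB inputs are converted to BT.601 luminance. When no pixel-spacing
#' metadata is present (always the case for PNG), spacing defaults to
#' 1 mm/pixel with a warning.
#'
#' @param path path to a single-frame DICOM or a PNG file.
#' @param case_id optional identifier; defaults to the file's PatientID
#'   (DICOM) or base name.
#' @return an [om_frame()].
#' @export
read_frame <- function(path, case_id = NULL) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  is_png <- grepl("\\.png$", path, ignore.case = TRUE)
  if (is_png) {
    arr <- png::readPNG(path) * 255
    pixels <- if (length(dim(arr)) == 3) {
      .bt601[1] * arr[, , 1] + .bt601[2] * arr[, , 2] + .bt601[3] * arr[, , 3]
    } else {
      arr
    }
    warn(sprintf("No pixel-spacing metadata in %s; assuming 1.0 mm/pixel.",
                 basename(path)))
    return(om_frame(pixels, c(1, 1),
                    case_id %||% sub("\\.png$", "", basename(path),
                                     ignore.case = TRUE)))
  }
  d <- read_dicom(path)
  pixels <- if (!is.null(d$channels) && d$samples_per_pixel == 3L) {
    .bt601[1] * d$channels[[1]] + .bt601[2] * d$channels[[2]] +
      .bt601[3] * d$channels[[3]]
  } else {
    d$pixels
  }
  if (identical(d$photometric, "MONOCHROME1")) {
    pixels <- max(pixels) - pixels
  }
  spacing <- d$spacing
  if (is.null(spacing) || any(!is.finite(spacing))) {
    warn(sprintf("No pixel-spacing tag in %s; assuming 1.0 mm/pixel.",
                 basename(path)))
    spacing <- c(1, 1)
  }
  om_frame(pixels, spacing,
           case_id %||% (if (is.na(d$case_id)) basename(path) else d$case_id))
}

#' Write a frame to disk
#'
#' @param frame an [om_frame()].
#' @param path output path ending in `.dcm` or `.png`.
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path) {
  stopifnot(inherits(frame, "om_frame"))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(round(pmin(pmax(frame$pixels, 0), 255)) / 255, path)
  } else {
    write_dicom(frame$pixels, path, spacing = frame$spacing,
                case_id = frame$case_id)
  }
  invisible(path)
}

#' Read / write a contour vertex file
#'
#' Contours are exchanged as two-column CSV files of floating-point `x`, `y`
#' pixel coordinates (0-based, pixel-centered), one vertex per row.
#'
#' @param path CSV file path.
#' @return numeric matrix with columns `x`, `y`.
#' @export
read_contour <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    x = readr::col_double(), y = readr::col_double()
  ), progress = FALSE)
  as.matrix(df[, c("x", "y")])
}

#' @rdname read_contour
#' @param contour numeric matrix with columns `x`, `y`.
#' @export
write_contour <- function(contour, path) {
  readr::write_csv(
    tibble::tibble(x = contour[, 1], y = contour[, 2]), path
  )
  invisible(path)
}

manifest_required_cols <- c("case_id", "image_path", "contour_path",
                            "mass_type", "shadow", "ca125", "menopausal")

#' Read and validate a cohort manifest
#'
#' The manifest is the tabular contract between pipeline stages: one row per
#' mass with image and contour paths, echotexture class, shadow flag, CA-125,
#' menopausal status, and (for training/evaluation only) the histology label.
#'
#' @param path manifest CSV path.
#' @param require_label if `TRUE`, a `label` column must be present.
#' @return a tibble, one validated row per case; `label` is `NA` when the
#'   column is absent.
#' @export
read_manifest <- function(path, require_label = FALSE) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(manifest_required_cols, names(df))
  if (length(missing)) {
    abort(sprintf("Manifest is missing required column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (!"label" %in% names(df)) {
    if (require_label) abort("Manifest has no `label` column.")
    df$label <- NA_character_
  }
  validate_manifest(df)
}

#' Validate an in-memory manifest tibble
#'
#' @param df tibble with the manifest schema.
#' @return the validated tibble (types coerced, flags as logical).
#' @export
validate_manifest <- function(df) {
  df <- tibble::as_tibble(df)
  bad <- which(!df$mass_type %in% c("solid", "cystic", "mixed"))
  if (length(bad)) {
    abort(sprintf("Unknown mass_type %s in manifest row %d.",
                  dQuote(df$mass_type[bad[1]]), bad[1]))
  }
  bad <- which(!df$menopausal %in% c("pre", "post"))
  if (length(bad)) {
    abort(sprintf("Unknown menopausal status %s in manifest row %d.",
                  dQuote(df$menopausal[bad[1]]), bad[1]))
  }
  df$ca125 <- as.numeric(df$ca125)
  bad <- which(!is.finite(df$ca125) | df$ca125 < 0)
  if (length(bad)) {
    abort(sprintf("Invalid ca125 value in manifest row %d (must be >= 0).",
                  bad[1]))
  }
  df$shadow <- as.logical(df$shadow)
  if (anyNA(df$shadow)) abort("`shadow` must be TRUE/FALSE.")
  if (!all(is.na(df$label))) {
    bad <- which(!df$label %in% c("benign", "malignant") & !is.na(df$label))
    if (length(bad)) {
      abort(sprintf("Unknown label %s in manifest row %d.",
                    dQuote(df$label[bad[1]]), bad[1]))
    }
  }
  df
}

#' @rdname read_manifest
#' @param df manifest tibble.
#' @export
write_manifest <- function(df, path) {
  readr::write_csv(df, path)
  invisible(path)
}
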