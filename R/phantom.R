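# Speckle phantom simulator: synthetic ultrasound-like frames with masses of
# the three echotexture classes, optional posterior acoustic shadows, and
# CA-125 values whose class-conditional distributions straddle the decision
# thresholds.

#' Phantom generator parameters
#'
#' Tissue, speckle, mass-appearance and biomarker settings of the simulator.
#' Intensity factors are multiplicative against the smooth background field;
#' `tau_*` scale the local speckle contrast (`1 + tau * (S - 1)` with `S` a
#' Rayleigh field of unit mean). Malignancy acts through larger boundary
#' irregularity and a higher texture-contrast parameter, the two image cues
#' the risk models are meant to pick up; `ca125_median_*` are the
#' class-conditional log-normal medians in U/mL.
#'
#' @param bg_mean,bg_sd mean and spread of the smooth tissue-intensity field
#'   (fraction of dynamic range).
#' @param tau_background speckle contrast outside the mass.
#' @param gain_cystic,gain_solid,gain_mixed_cyst,gain_nodule interior
#'   intensity factors.
#' @param tau_interior_benign,tau_interior_malignant texture-contrast
#'   parameter of echogenic interiors.
#' @param tau_cyst_benign,tau_cyst_malignant texture contrast of cystic
#'   interiors (faint internal echoes when malignant).
#' @param heterogeneity_benign,heterogeneity_malignant amplitude of the
#'   low-frequency interior heterogeneity field.
#' @param irregularity_benign,irregularity_malignant peak radial contour
#'   noise as a fraction of equivalent radius.
#' @param shadow_factor multiplicative attenuation of the trapezoidal band
#'   below the mass when a shadow is rendered.
#' @param ca125_median_benign,ca125_median_malignant_pre,ca125_median_malignant_post
#'   log-normal medians (U/mL); defaults 25 / 250 / 150 put the
#'   class-conditional medians on opposite sides of the 200 (pre) and 71
#'   (post) U/mL decision thresholds.
#' @param ca125_sdlog log-scale spread of CA-125.
#' @param r_eq_range equivalent-radius range of the mass in pixels.
#' @return list of class `phantom_params`.
#' @export
phantom_params <- function(bg_mean = 0.50, bg_sd = 0.06,
                           tau_background = 0.70,
                           gain_cystic = 0.16, gain_solid = 1.35,
                           gain_mixed_cyst = 0.20, gain_nodule = 1.40,
                           tau_interior_benign = 0.50,
                           tau_interior_malignant = 1.10,
                           tau_cyst_benign = 0.20,
                           tau_cyst_malignant = 0.60,
                           heterogeneity_benign = 0.05,
                           heterogeneity_malignant = 0.30,
                           irregularity_benign = 0.03,
                           irregularity_malignant = 0.12,
                           shadow_factor = 0.35,
                           ca125_median_benign = 25,
                           ca125_median_malignant_pre = 250,
                           ca125_median_malignant_post = 150,
                           ca125_sdlog = 0.8,
                           r_eq_range = c(18, 28)) {
  structure(as.list(environment()), class = "phantom_params")
}

#' Phantom specification
#'
#' Deterministic recipe for one synthetic case; the seed fully determines
#' every sampled value.
#'
#' @param mass_type `"solid"`, `"cystic"` or `"mixed"`.
#' @param malignant logical.
#' @param shadow render a posterior acoustic shadow?
#' @param menopausal `"pre"` or `"post"`.
#' @param seed integer seed.
#' @param image_size (rows, cols), at least 64 x 64.
#' @param pixel_spacing mm per pixel (> 0).
#' @param params a [phantom_params()] list.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(mass_type, malignant, shadow = FALSE,
                         menopausal = "post", seed = 1L,
                         image_size = c(128, 128), pixel_spacing = 0.3,
                         params = phantom_params()) {
  match_mass_type(mass_type)
  match_menopausal(menopausal)
  if (any(image_size < 64)) abort("`image_size` must be at least 64 x 64.")
  if (pixel_spacing <= 0) abort("`pixel_spacing` must be > 0.")
  structure(list(mass_type = mass_type, malignant = isTRUE(malignant),
                 shadow = isTRUE(shadow), menopausal = menopausal,
                 seed = as.integer(seed), image_size = as.integer(image_size),
                 pixel_spacing = pixel_spacing, params = params),
            class = "phantom_spec")
}

# Smooth unit-mean Rayleigh speckle field.
.speckle_field <- function(h, w) {
  sigma <- sqrt(2 / pi)                  # unit-mean Rayleigh scale
  s <- matrix(sigma * sqrt(-2 * log(runif(h * w))), h, w)
  s <- EBImage::gblur(s, sigma = 1)
  s / mean(s)
}

# Smooth low-frequency field, zero mean, unit sd.
.smooth_field <- function(h, w, sigma) {
  f <- EBImage::gblur(matrix(rnorm(h * w), h, w), sigma = sigma)
  (f - mean(f)) / sd(f)
}

# Star-shaped mass contour: ellipse radius plus low-order harmonic noise.
.mass_contour <- function(center, r_eq, aspect, rot, irregularity,
                          n_vertices = 96) {
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  a <- r_eq / sqrt(aspect); b <- r_eq * sqrt(aspect)
  phi <- theta - rot
  r <- a * b / sqrt((b * cos(phi))^2 + (a * sin(phi))^2)
  if (irregularity > 0) {
    f <- numeric(length(theta))
    for (h in 2:7) f <- f + rnorm(1) * cos(h * theta) + rnorm(1) * sin(h * theta)
    f <- f / max(abs(f)) * irregularity * r_eq
    r <- pmax(r + f, 0.3 * r_eq)
  }
  cbind(x = center[1] + r * cos(theta), y = center[2] + r * sin(theta))
}

#' Generate one synthetic phantom case
#'
#' Builds a speckled frame (multiplicative Rayleigh texture over a smooth
#' tissue-intensity field), inserts an ellipse-derived mass of the requested
#' echotexture class (cystic: hypoechoic interior; solid: hyperechoic
#' textured interior; mixed: cystic region with one or two solid mural
#' nodules), optionally attenuates a trapezoidal band below the mass
#' (acoustic shadow), and draws a CA-125 level from the class-conditional
#' log-normal.
#'
#' @param spec a [phantom_spec()].
#' @return list of class `phantom_case` with elements `frame`
#'   ([om_frame()]), `annotation` ([om_annotation()]), `clinical`
#'   ([om_clinical()]), `label` (`"benign"`/`"malignant"`), `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  p <- spec$params
  withr::with_seed(spec$seed, {
    h <- spec$image_size[1]; w <- spec$image_size[2]
    r_eq <- runif(1, p$r_eq_range[1], p$r_eq_range[2])
    aspect <- runif(1, 0.65, 1)
    rot <- runif(1, 0, pi)
    center <- c(w * 0.5 + runif(1, -4, 4), h * 0.45 + runif(1, -4, 4))
    irregularity <- if (spec$malignant) p$irregularity_malignant else
      p$irregularity_benign
    contour <- .mass_contour(center, r_eq, aspect, rot, irregularity)
    r_max <- max(sqrt((contour[, 1] - center[1])^2 +
                        (contour[, 2] - center[2])^2))
    if (center[1] - r_max < 2 || center[1] + r_max > w - 3 ||
        center[2] - r_max < 2 || center[2] + r_max > h - 3) {
      abort("Mass does not fit in the frame; enlarge `image_size` or shrink `r_eq_range`.")
    }
    mask <- rasterize_contour(contour, c(h, w))

    bg <- p$bg_mean + p$bg_sd * .smooth_field(h, w, sigma = 12)
    speckle <- .speckle_field(h, w)
    het <- .smooth_field(h, w, sigma = 3)

    gain <- matrix(1, h, w)
    tau <- matrix(p$tau_background, h, w)
    tau_int <- if (spec$malignant) p$tau_interior_malignant else
      p$tau_interior_benign
    tau_cyst <- if (spec$malignant) p$tau_cyst_malignant else p$tau_cyst_benign
    het_amp <- if (spec$malignant) p$heterogeneity_malignant else
      p$heterogeneity_benign

    if (spec$mass_type == "cystic") {
      gain[mask] <- p$gain_cystic
      tau[mask] <- tau_cyst
    } else if (spec$mass_type == "solid") {
      gain[mask] <- p$gain_solid * (1 + het_amp * het[mask])
      tau[mask] <- tau_int
    } else {
      gain[mask] <- p$gain_mixed_cyst
      tau[mask] <- tau_cyst
      n_nod <- sample(1:2, 1)
      for (k in seq_len(n_nod)) {
        ang <- runif(1, 0, 2 * pi)
        d <- runif(1, 0, 0.45) * r_eq
        rn <- runif(1, 0.25, 0.40) * r_eq
        nc <- center + d * c(cos(ang), sin(ang))
        xs <- matrix(rep(0:(w - 1), each = h), h)
        ys <- matrix(rep(0:(h - 1), w), h)
        nod <- mask & ((xs - nc[1])^2 + (ys - nc[2])^2 <= rn^2)
        gain[nod] <- p$gain_nodule * (1 + het_amp * het[nod])
        tau[nod] <- tau_int
      }
    }

    img <- bg * gain * (1 + tau * (speckle - 1))

    if (spec$shadow) {
      xs0 <- 0:(w - 1)
      in_mask_cols <- which(colSums(mask) > 0) - 1L
      x_lo <- min(in_mask_cols); x_hi <- max(in_mask_cols)
      y_bot <- max(which(rowSums(mask) > 0)) - 1L
      taper <- 6
      att <- rep(1, w)
      core <- xs0 >= x_lo & xs0 <= x_hi
      att[core] <- p$shadow_factor
      ramp <- xs0 >= x_lo - taper & xs0 < x_lo
      att[ramp] <- 1 - (1 - p$shadow_factor) * (1 - (x_lo - xs0[ramp]) / taper)
      ramp <- xs0 > x_hi & xs0 <= x_hi + taper
      att[ramp] <- 1 - (1 - p$shadow_factor) * (1 - (xs0[ramp] - x_hi) / taper)
      if (y_bot + 2 <= h) {
        rows_below <- (y_bot + 2):h
        img[rows_below, ] <- sweep(img[rows_below, , drop = FALSE], 2, att, `*`)
      }
    }

    pixels <- round(pmin(pmax(img, 0), 1.2) / 1.2 * 255)

    med <- if (!spec$malignant) p$ca125_median_benign
    else if (spec$menopausal == "pre") p$ca125_median_malignant_pre
    else p$ca125_median_malignant_post
    ca125 <- rlnorm(1, meanlog = log(med), sdlog = p$ca125_sdlog)

    structure(list(
      frame = om_frame(pixels, rep(spec$pixel_spacing, 2),
                       case_id = sprintf("phantom_%d", spec$seed)),
      annotation = om_annotation(spec$mass_type, contour, spec$shadow),
      clinical = om_clinical(ca125, spec$menopausal),
      label = if (spec$malignant) "malignant" else "benign",
      spec = spec
    ), class = "phantom_case")
  })
}

#' Generate a synthetic cohort
#'
#' Draws `n` phantom cases with a fixed malignancy count
#' `round(n * prevalence)`, echotexture mix, benign-skewed shadow prevalence,
#' and menopausal mix, each case from its own derived seed so the cohort is
#' reproducible under partial regeneration.
#'
#' @param n number of cases (> 0).
#' @param prevalence malignant fraction in `[0, 1]`; default 0.515, the
#'   prevalence of the retrospective cohort the system was developed on.
#' @param mix named type proportions summing to 1; default mirrors the
#'   93/67/79 solid/cystic(liquid)/mixed composition of that cohort.
#' @param seed master integer seed.
#' @param p_shadow_benign,p_shadow_malignant shadow probability per class
#'   (shadows are an established benign sign).
#' @param p_post probability of postmenopausal status.
#' @param params a [phantom_params()].
#' @param image_size,pixel_spacing forwarded to [phantom_spec()].
#' @return list with `cases` (list of `phantom_case`) and `manifest`
#'   (tibble: case_id, mass_type, shadow, ca125, menopausal, label, seed).
#' @export
generate_cohort <- function(n, prevalence = 0.515,
                            mix = c(solid = 93, cystic = 67, mixed = 79) / 239,
                            seed = 1L,
                            p_shadow_benign = 0.30, p_shadow_malignant = 0.05,
                            p_post = 0.62,
                            params = phantom_params(),
                            image_size = c(128, 128), pixel_spacing = 0.3) {
  if (n <= 0) abort("`n` must be a positive count.")
  if (prevalence < 0 || prevalence > 1) abort("`prevalence` must lie in [0, 1].")
  if (abs(sum(mix) - 1) > 1e-6) abort("`mix` proportions must sum to 1.")
  n_mal <- round(n * prevalence)
  assign_df <- withr::with_seed(seed, {
    malignant <- sample(c(rep(TRUE, n_mal), rep(FALSE, n - n_mal)))
    mass_type <- sample(names(mix), n, replace = TRUE, prob = mix)
    shadow <- runif(n) < ifelse(malignant, p_shadow_malignant, p_shadow_benign)
    menopausal <- ifelse(runif(n) < p_post, "post", "pre")
    tibble::tibble(malignant, mass_type, shadow, menopausal)
  })
  cases <- purrr::map(seq_len(n), function(i) {
    cs <- derive_seed(seed, i)
    case <- generate_phantom(phantom_spec(
      mass_type = assign_df$mass_type[i], malignant = assign_df$malignant[i],
      shadow = assign_df$shadow[i], menopausal = assign_df$menopausal[i],
      seed = cs, image_size = image_size, pixel_spacing = pixel_spacing,
      params = params
    ))
    case$frame$case_id <- sprintf("case_%04d", i)
    case
  })
  manifest <- purrr::map2_dfr(cases, seq_len(n), function(case, i) {
    tibble::tibble(
      case_id = case$frame$case_id,
      mass_type = case$annotation$mass_type,
      shadow = case$annotation$shadow_present,
      ca125 = case$clinical$ca125,
      menopausal = case$clinical$menopausal,
      label = case$label,
      seed = case$spec$seed
    )
  })
  list(cases = cases, manifest = manifest)
}

#' Write a cohort to disk
#'
#' Frames go to single-frame grayscale DICOM (or PNG), contours to CSV
#' vertex files, and the manifest to `manifest.csv` with image/contour paths.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @param format `"dcm"` or `"png"`.
#' @return path of the written manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("dcm", "png")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- purrr::map_dfr(cohort$cases, function(case) {
    id <- case$frame$case_id
    ipath <- file.path(dir, paste0(id, ".", format))
    cpath <- file.path(dir, paste0(id, "_contour.csv"))
    write_frame(case$frame, ipath)
    write_contour(case$annotation$contour, cpath)
    tibble::tibble(case_id = id, image_path = ipath, contour_path = cpath)
  })
  manifest <- dplyr::left_join(rows, cohort$manifest, by = "case_id")
  mpath <- file.path(dir, "manifest.csv")
  write_manifest(manifest, mpath)
  invisible(mpath)
}

#' Contour radial variance (boundary-irregularity statistic)
#'
#' Variance of vertex radii about the centroid, normalized by the squared
#' mean radius; used to verify that malignant phantoms carry more irregular
#' boundaries.
#'
#' @param contour contour matrix (columns `x`, `y`).
#' @return non-negative scalar.
#' @export
contour_radial_variance <- function(contour) {
  ctr <- polygon_centroid(contour)
  r <- sqrt((contour[, 1] - ctr[1])^2 + (contour[, 2] - ctr[2])^2)
  var(r / mean(r))
}
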