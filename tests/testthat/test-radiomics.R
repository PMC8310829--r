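frame_from <- function(mat, spacing = c(1, 1)) {
  om_frame(mat, spacing, "t")
}

test_that("discretization maps ROI range to 1..n_bins per the bin formula", {
  px <- matrix(rep(0:255, length.out = 16 * 16), 16, 16)
  mask <- matrix(TRUE, 16, 16)
  lv <- discretize(px, mask, discretization_config(64))
  expect_identical(sort(unique(as.vector(lv))), 1:64)

  const <- discretize(matrix(7, 5, 5), matrix(TRUE, 5, 5))
  expect_true(all(const == 1L))

  # brute-force formula application, random 8x8 ROI, 4 bins
  withr::with_seed(31, {
    px <- matrix(runif(64, 10, 90), 8, 8)
    mask <- matrix(runif(64) < 0.8, 8, 8)
    mask[1:2, 1:2] <- TRUE
  })
  lv <- discretize(px, mask, discretization_config(4))
  v <- px[mask]; mn <- min(v); mx <- max(v)
  manual <- pmin(1L + as.integer(floor(4 * (px[mask] - mn) / (mx - mn))), 4L)
  expect_identical(lv[mask], manual)
  expect_true(all(is.na(lv[!mask])))
  expect_error(discretize(px, mask & FALSE), "empty")
})

test_that("shape features agree with geometry on squares, disks and hulls", {
  sq <- rasterize_contour(cbind(x = c(10, 20, 20, 10), y = c(10, 10, 20, 20)),
                          c(40, 40))
  sf <- shape_features(sq, c(1, 1))
  expect_equal(sf[["shape_area_mm2"]], 100)
  expect_equal(sf[["shape_solidity"]], 1.0)
  expect_equal(sf[["shape_feret_max_mm"]], sqrt(2) * 10, tolerance = 1e-6)

  disk <- rasterize_contour(circle_contour(64, 64, 50, n = 720), c(130, 130))
  sfd <- shape_features(disk, c(1, 1))
  expect_gte(sfd[["shape_circularity"]], 0.95)
  expect_lte(sfd[["shape_circularity"]], 1.05)
  expect_equal(sfd[["shape_equiv_diameter_mm"]], 100, tolerance = 0.01)
  expect_lte(sfd[["shape_eccentricity"]], 0.1)

  # spacing scales areas quadratically and lengths linearly
  sf2 <- shape_features(sq, c(0.5, 0.5))
  expect_equal(sf2[["shape_area_mm2"]], 25)
  expect_equal(sf2[["shape_feret_max_mm"]], sf[["shape_feret_max_mm"]] / 2)

  # random blobs: convex hull area against an independent monotone-chain hull
  for (seed in 1:8) {
    case <- generate_phantom(phantom_spec("solid", seed %% 2 == 0, seed = seed))
    mask <- rasterize_contour(case$annotation$contour, dim(case$frame$pixels))
    sfb <- shape_features(mask, c(1, 1))
    idx <- which(mask)
    yy <- (idx - 1) %% nrow(mask); xx <- (idx - 1) %/% nrow(mask)
    corners <- cbind(c(xx - 0.5, xx + 0.5, xx - 0.5, xx + 0.5),
                     c(yy - 0.5, yy - 0.5, yy + 0.5, yy + 0.5))
    hull_area <- sfb[["shape_area_mm2"]] / sfb[["shape_solidity"]]
    expect_lte(abs(hull_area - oracle_hull_area(corners)), 1)
  }
})

test_that("GLCM matches hand enumeration on degenerate and checkerboard ROIs", {
  const <- matrix(3L, 6, 6)
  f <- glcm_features(const, distances = 1L)
  expect_equal(f[["glcm_d1_contrast"]], 0)
  expect_equal(f[["glcm_d1_asm"]], 1)
  expect_equal(f[["glcm_d1_inverse_difference"]], 1)
  expect_equal(f[["glcm_d1_correlation"]], 1)

  checker <- outer(1:6, 1:6, function(i, j) ((i + j) %% 2) + 1L)
  P <- adnexdss:::.glcm_matrix(checker, c(0L, 1L), 2L)
  P <- P / sum(P)
  expect_equal(unclass(P), matrix(c(0, 0.5, 0.5, 0), 2), ignore_attr = TRUE)
  fs <- adnexdss:::.glcm_feature_set(P)
  expect_equal(fs[["contrast"]], 1)
  expect_equal(fs[["asm"]], 0.5)
})

test_that("GLRLM matches hand enumeration on single-row cases", {
  row1 <- matrix(c(1L, 1L, 1L, 2L), 1, 4)
  R <- adnexdss:::.glrlm_matrix(row1, c(0L, 1L), 2L)
  expect_equal(R[1, 3], 1)
  expect_equal(R[2, 1], 1)
  expect_equal(sum(R), 2)
  expect_equal(sum(R) / 4, 0.5)  # run percentage along this direction

  # constant single row: one run of length n dominates LRE
  constant <- matrix(2L, 1, 8)
  Rc <- adnexdss:::.glrlm_matrix(constant, c(0L, 1L), 2L)
  expect_equal(Rc[2, 8], 1)
  f <- oracle_glrlm_features(Rc, 8)
  expect_equal(f[["lre"]], 64)
})

test_that("GLSZM zones match hand enumeration", {
  const <- matrix(2L, 5, 5)
  z <- glszm_zones(const)
  expect_equal(nrow(z), 1)
  f <- glszm_features(const)
  expect_equal(f[["glszm_zp"]], 1 / 25)

  # two disjoint same-level blobs, sizes 3 and 5
  lv <- matrix(NA_integer_, 6, 6)
  lv[1, 1:3] <- 1L
  lv[5, 1:3] <- 1L; lv[6, 2:3] <- 1L
  z2 <- glszm_zones(lv)
  expect_setequal(z2$size, c(3, 5))
})

test_that("texture families equal brute-force oracles on random ROIs", {
  offs <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
  for (seed in 1:12) {
    lv <- random_levels_roi(seed)
    nl <- max(lv, na.rm = TRUE)
    np <- sum(!is.na(lv))
    # GLCM, distance 1
    got <- glcm_features(lv, distances = 1L)
    oracle <- rowMeans(vapply(offs, function(o) {
      P <- oracle_glcm(lv, o[1], o[2], nl)
      oracle_glcm_features(P / sum(P))
    }, numeric(8)))
    expect_equal(unname(got), unname(oracle), tolerance = 1e-12)
    # GLRLM
    gotr <- glrlm_features(lv)
    oracler <- rowMeans(vapply(offs, function(o) {
      oracle_glrlm_features(oracle_glrlm(lv, o[1], o[2], nl), np)
    }, numeric(7)))
    expect_equal(unname(gotr), unname(oracler), tolerance = 1e-12)
    # GLSZM
    gotz <- glszm_features(lv)
    oraclez <- oracle_glszm_features(oracle_glszm_zones(lv), np)
    expect_equal(unname(gotz), unname(oraclez), tolerance = 1e-12)
  }
})

test_that("angle-averaged texture features are invariant to 90-degree rotation", {
  case <- generate_phantom(phantom_spec("solid", TRUE, seed = 88))
  mask <- rasterize_contour(case$annotation$contour, dim(case$frame$pixels))
  cr <- adnexdss:::.crop_to_mask(case$frame$pixels, mask)
  lv <- discretize(cr$mat, cr$mask)
  rot <- function(m) t(m)[, nrow(m):1, drop = FALSE]   # 90-degree rotation
  lv_rot <- rot(lv)
  expect_equal(glcm_features(lv), glcm_features(lv_rot), tolerance = 1e-8)
  expect_equal(glrlm_features(lv), glrlm_features(lv_rot), tolerance = 1e-8)
  expect_equal(glszm_features(lv), glszm_features(lv_rot), tolerance = 1e-8)
})

test_that("full extraction is complete, finite and scale-invariant in texture", {
  case <- generate_phantom(phantom_spec("mixed", TRUE, seed = 12))
  mask <- rasterize_contour(case$annotation$contour, dim(case$frame$pixels))
  fv <- extract_features(case$frame, mask, "mixed")
  expect_true(all(is.finite(fv)))
  expect_true(any(startsWith(names(fv), "solidsub_")))
  expect_true(all(c("fo_mean", "shape_area_mm2", "glcm_d1_contrast",
                    "glcm_d4_entropy", "glrlm_sre", "glszm_zp") %in% names(fv)))
  # same catalogue for solid and cystic (no subregion namespace)
  fv_solid <- extract_features(case$frame, mask, "solid")
  expect_identical(names(fv_solid),
                   setdiff(names(fv), grep("^solidsub_", names(fv), value = TRUE)))

  # doubling intensities leaves features on discretized levels unchanged
  f2 <- case$frame; f2$pixels <- f2$pixels * 2
  fv2 <- extract_features(f2, mask, "solid")
  tex <- grep("^(glcm|glrlm|glszm)_", names(fv_solid), value = TRUE)
  expect_equal(fv2[tex], fv_solid[tex], tolerance = 1e-12)
})

test_that("constructed phantom contrasts surface in first-order features", {
  solid <- generate_phantom(phantom_spec("solid", FALSE, seed = 5))
  cystic <- generate_phantom(phantom_spec("cystic", FALSE, seed = 5))
  ms <- rasterize_contour(solid$annotation$contour, dim(solid$frame$pixels))
  mc <- rasterize_contour(cystic$annotation$contour, dim(cystic$frame$pixels))
  fs <- extract_features(solid$frame, ms, "solid")
  fc <- extract_features(cystic$frame, mc, "cystic")
  expect_gt(fs[["fo_mean"]], fc[["fo_mean"]])
})
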