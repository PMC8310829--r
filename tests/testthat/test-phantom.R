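test_that("identical specs generate bit-identical cases", {
  s <- phantom_spec("mixed", TRUE, shadow = TRUE, menopausal = "pre", seed = 17)
  a <- generate_phantom(s)
  b <- generate_phantom(s)
  expect_identical(a$frame$pixels, b$frame$pixels)
  expect_identical(a$annotation$contour, b$annotation$contour)
  expect_identical(a$clinical$ca125, b$clinical$ca125)
  c2 <- generate_phantom(phantom_spec("mixed", TRUE, shadow = TRUE,
                                      menopausal = "pre", seed = 18))
  expect_false(identical(a$frame$pixels, c2$frame$pixels))
})

test_that("cystic interiors are hypoechoic; solid interiors hyperechoic", {
  cys <- generate_phantom(phantom_spec("cystic", FALSE, seed = 2))
  m <- rasterize_contour(cys$annotation$contour, dim(cys$frame$pixels))
  expect_lt(mean(cys$frame$pixels[m]), mean(cys$frame$pixels[!m]))
  sol <- generate_phantom(phantom_spec("solid", FALSE, seed = 2))
  ms <- rasterize_contour(sol$annotation$contour, dim(sol$frame$pixels))
  expect_gt(mean(sol$frame$pixels[ms]), mean(sol$frame$pixels[!ms]))
})

test_that("acoustic shadow attenuates the band below the mass", {
  on <- generate_phantom(phantom_spec("solid", FALSE, shadow = TRUE, seed = 9))
  off <- generate_phantom(phantom_spec("solid", FALSE, shadow = FALSE, seed = 9))
  mask <- rasterize_contour(on$annotation$contour, dim(on$frame$pixels))
  rows_below <- (max(which(rowSums(mask) > 0)) + 2):nrow(mask)
  cols <- range(which(colSums(mask) > 0))
  band <- function(px) mean(px[rows_below, cols[1]:cols[2]])
  expect_lt(band(on$frame$pixels), 0.6 * band(off$frame$pixels))
})

test_that("contours always fit, rasterize to >= 50 px, and stay simple", {
  for (seed in 1:20) {
    case <- generate_phantom(phantom_spec(
      sample(c("solid", "cystic", "mixed"), 1),
      malignant = seed %% 2 == 0, seed = seed
    ))
    ct <- case$annotation$contour
    expect_true(all(ct[, 1] >= 0 & ct[, 1] <= 127))
    expect_true(all(ct[, 2] >= 0 & ct[, 2] <= 127))
    expect_gte(sum(rasterize_contour(ct, c(128, 128))), 50)
    expect_true(adnexdss:::is_simple_polygon(ct))
  }
  expect_error(
    generate_phantom(phantom_spec("solid", FALSE, seed = 1,
                                  image_size = c(64, 64),
                                  params = phantom_params(
                                    r_eq_range = c(30, 32)))),
    "does not fit"
  )
  expect_error(phantom_spec("solid", FALSE, image_size = c(32, 32)),
               "at least 64")
})

test_that("malignant phantoms have more irregular boundaries (rank test)", {
  rv <- function(malignant, seeds) {
    vapply(seeds, function(s) {
      case <- generate_phantom(phantom_spec("solid", malignant, seed = s,
                                            image_size = c(96, 96),
                                            params = phantom_params(
                                              r_eq_range = c(13, 19))))
      contour_radial_variance(case$annotation$contour)
    }, numeric(1))
  }
  ben <- rv(FALSE, 1:100)
  mal <- rv(TRUE, 101:200)
  p <- wilcox.test(mal, ben, alternative = "greater")$p.value
  expect_lt(p, 0.01)
})

test_that("cohorts honour prevalence counts exactly", {
  coh <- generate_cohort(239, prevalence = 0.515, seed = 3,
                         image_size = c(96, 96),
                         params = phantom_params(r_eq_range = c(13, 19)))
  expect_equal(sum(coh$manifest$label == "malignant"), 123)
  expect_equal(nrow(coh$manifest), 239)

  coh2 <- generate_cohort(35, prevalence = 0.571, seed = 3,
                          image_size = c(96, 96),
                          params = phantom_params(r_eq_range = c(13, 19)))
  expect_equal(sum(coh2$manifest$label == "malignant"), 20)

  coh0 <- generate_cohort(10, prevalence = 0, seed = 3,
                          image_size = c(96, 96),
                          params = phantom_params(r_eq_range = c(13, 19)))
  expect_equal(sum(coh0$manifest$label == "malignant"), 0)

  expect_error(generate_cohort(0), "positive")
  expect_error(generate_cohort(10, prevalence = 1.2), "0, 1")
  expect_error(generate_cohort(10, mix = c(solid = 0.5, cystic = 0.5,
                                           mixed = 0.5)), "sum to 1")
})

test_that("same master seed reproduces the same cohort", {
  a <- generate_cohort(6, seed = 21, image_size = c(96, 96),
                       params = phantom_params(r_eq_range = c(13, 19)))
  b <- generate_cohort(6, seed = 21, image_size = c(96, 96),
                       params = phantom_params(r_eq_range = c(13, 19)))
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$cases[[4]]$frame$pixels, b$cases[[4]]$frame$pixels)
})

test_that("class-conditional CA-125 straddles the decision thresholds", {
  # Monte-Carlo through the generator's own sampling path at n = 10^4
  draw <- function(malignant, menopausal, n, seed) {
    p <- phantom_params()
    med <- if (!malignant) p$ca125_median_benign
    else if (menopausal == "pre") p$ca125_median_malignant_pre
    else p$ca125_median_malignant_post
    withr::with_seed(seed, rlnorm(n, log(med), p$ca125_sdlog))
  }
  for (meno in c("pre", "post")) {
    mal <- draw(TRUE, meno, 1e4, 71)
    ben <- draw(FALSE, meno, 1e4, 72)
    p_mal <- mean(ca125_above(mal, meno))
    p_ben <- mean(ca125_above(ben, meno))
    expect_gt(p_mal, p_ben)
    expect_gt(p_mal, 0.5)
    expect_lt(p_ben, 0.15)
  }
  # and through generate_phantom itself on a smaller sample
  ca <- vapply(1:25, function(s) {
    generate_phantom(phantom_spec("solid", TRUE, menopausal = "post",
                                  seed = s))$clinical$ca125
  }, numeric(1))
  cb <- vapply(26:50, function(s) {
    generate_phantom(phantom_spec("solid", FALSE, menopausal = "post",
                                  seed = s))$clinical$ca125
  }, numeric(1))
  expect_gt(median(ca), median(cb))
})
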