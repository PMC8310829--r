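test_that("ICC(1,1) matches one-way ANOVA mean squares", {
  # 3 masses x 3 variants, hand-checkable via aov as the oracle
  values <- c(10, 11, 9, 20, 22, 21, 31, 30, 29)
  subject <- rep(c("a", "b", "c"), each = 3)
  fit <- summary(stats::aov(values ~ factor(subject)))[[1]]
  msb <- fit[["Mean Sq"]][1]; msw <- fit[["Mean Sq"]][2]
  expected <- (msb - msw) / (msb + 2 * msw)
  got <- icc_oneway(values, subject)
  expect_equal(got$icc, expected)
  expect_false(got$degenerate)
  expect_equal(got$k, 3)
})

test_that("variant-invariant features score ICC 1; constants are degenerate", {
  df <- tibble::tibble(
    case_id = rep(c("m1", "m2", "m3"), each = 4), variant = rep(1:4, 3),
    f_invariant = rep(c(1, 5, 9), each = 4),
    f_constant = 2,
    f_noisy = rnorm(12)
  )
  rep_ <- feature_stability(df, threshold = 0.75)
  expect_equal(rep_$icc[rep_$feature == "f_invariant"], 1)
  expect_true(rep_$selected[rep_$feature == "f_invariant"])
  expect_true(rep_$degenerate[rep_$feature == "f_constant"])
  expect_false(rep_$selected[rep_$feature == "f_constant"])
})

test_that("pure-noise features average near-zero ICC over 100 seeds", {
  iccs <- vapply(1:100, function(s) {
    withr::with_seed(s, {
      icc_oneway(rnorm(30), rep(1:10, each = 3))$icc
    })
  }, numeric(1))
  expect_lt(mean(iccs), 0.1)
})

test_that("ragged variant counts fall back to harmonic-mean k with warning", {
  values <- c(1, 2, 1.5, 10, 11, 30, 31, 29, 30.5)
  subject <- c("a", "a", "a", "b", "b", "c", "c", "c", "c")
  expect_warning(got <- icc_oneway(values, subject), "harmonic")
  expect_equal(got$k, 3 / (1 / 3 + 1 / 2 + 1 / 4))
  expect_error(icc_oneway(1:3, c("a", "a", "b")), ">= 2")
})

test_that("panel selection orders by ICC, is order-invariant, and errors empty", {
  df <- tibble::tibble(
    case_id = rep(c("m1", "m2", "m3", "m4"), each = 3), variant = rep(1:3, 4),
    alpha = rep(c(1, 4, 9, 16), each = 3) + rnorm(12, sd = 0.4),
    beta = rep(c(2, 8, 1, 9), each = 3) + rnorm(12, sd = 2),
    gamma = rnorm(12)
  )
  rep_ <- feature_stability(df, threshold = 0)
  panel <- select_panel(rep_, "solid")
  expect_setequal(panel, c("alpha", "beta", "gamma"))
  icc <- attr(panel, "icc")
  expect_true(all(diff(icc) <= 0))

  # invariance to feature-column and case-row order
  df2 <- df[sample(nrow(df)), c("case_id", "variant", "gamma", "alpha", "beta")]
  rep2 <- feature_stability(df2, threshold = 0)
  expect_equal(tidy(rep_), tidy(rep2))

  expect_error(select_panel(rep_, "solid", threshold = 1.01), "threshold")
  expect_error(select_panel(rep_, "papillary"), "mass_type")

  # round-trip through the panel file
  path <- withr::local_tempfile(fileext = ".json")
  write_panel(panel, path)
  back <- read_panel(path)
  expect_identical(as.character(back), as.character(panel))
  expect_identical(attr(back, "mass_type"), "solid")
})

test_that("heavier contour perturbation never helps feature stability", {
  # same six phantom masses re-extracted under increasing amplitude
  cases <- lapply(1:6, function(s) {
    generate_phantom(phantom_spec(c("solid", "cystic")[s %% 2 + 1],
                                  malignant = s <= 3, seed = 400 + s))
  })
  features <- c("fo_mean", "shape_area_mm2", "shape_circularity",
                "glcm_d1_contrast", "glrlm_sre")
  mean_icc <- vapply(c(0.02, 0.15), function(amp) {
    reps <- vapply(1:2, function(r) {
      df <- dplyr::bind_rows(lapply(seq_along(cases), function(i) {
        extract_case_features(
          cases[[i]]$frame, cases[[i]]$annotation$contour,
          cases[[i]]$annotation$mass_type,
          perturbation_config(4, amp, seed = 1000 * r + i),
          include_original = FALSE
        )
      }))
      rep_ <- feature_stability(df[, c("case_id", "variant", features)])
      mean(rep_$icc, na.rm = TRUE)
    }, numeric(1))
    mean(reps)
  }, numeric(1))
  expect_gte(mean_icc[1], mean_icc[2])
})
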