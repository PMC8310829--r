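test_that("CA-125 threshold comparison is menopause-corrected and strict", {
  expect_true(ca125_above(205, "pre"))
  expect_true(ca125_above(205, "post"))
  expect_false(ca125_above(12, "post"))
  # boundary values are not 'higher than' the threshold
  expect_false(ca125_above(71, "post"))
  expect_false(ca125_above(200, "pre"))
  expect_true(ca125_above(71.01, "post"))
  expect_false(ca125_above(100, "pre"))
  expect_true(ca125_above(100, "post"))
  expect_error(ca125_above(-1, "post"), "non-negative")
  expect_error(ca125_above(50, "perimenopausal"), "menopausal")
  # configurable thresholds
  thr <- dss_thresholds(ca125_post = 35, ca125_pre = 100)
  expect_true(ca125_above(50, "post", thr))
})

test_that("risk integration matches the exhaustive three-rule truth table", {
  combos <- expand.grid(radiomic = c("very_low", "medium_high"),
                        shadow = c(FALSE, TRUE), above = c(FALSE, TRUE),
                        stringsAsFactors = FALSE)
  # hand-written truth table: CA-125 above dominates; then shadow; then model
  expected_final <- character(8)
  expected_route <- character(8)
  for (i in seq_len(8)) {
    if (combos$above[i]) {
      expected_final[i] <- "medium_high"; expected_route[i] <- "ca125_override"
    } else if (combos$shadow[i]) {
      expected_final[i] <- "very_low"; expected_route[i] <- "shadow_override"
    } else {
      expected_final[i] <- combos$radiomic[i]; expected_route[i] <- "radiomic"
    }
  }
  got <- integrate_risk(combos$radiomic, combos$shadow, combos$above)
  expect_identical(got$final, expected_final)
  expect_identical(got$route, expected_route)
  # the two published override examples
  expect_identical(integrate_risk("medium_high", TRUE, FALSE)$final, "very_low")
  expect_identical(integrate_risk("very_low", FALSE, TRUE)$final, "medium_high")
  # radiomic route echoes the model prediction exactly
  rad <- integrate_risk(c("very_low", "medium_high"), FALSE, FALSE)
  expect_identical(rad$final, c("very_low", "medium_high"))
})

test_that("raising CA-125 can never demote a medium-high decision", {
  set.seed(7)
  for (i in 1:50) {
    rad <- sample(c("very_low", "medium_high"), 1)
    shadow <- sample(c(TRUE, FALSE), 1)
    meno <- sample(c("pre", "post"), 1)
    ca1 <- runif(1, 0, 400)
    ca2 <- ca1 + runif(1, 0, 400)
    d1 <- integrate_risk(rad, shadow, ca125_above(ca1, meno))$final
    d2 <- integrate_risk(rad, shadow, ca125_above(ca2, meno))$final
    if (d1 == "medium_high") expect_identical(d2, "medium_high")
  }
})

test_that("radiomic prediction is demanded exactly when no override applies", {
  expect_error(integrate_risk(NA, FALSE, FALSE), "required")
  expect_silent(integrate_risk(NA, TRUE, FALSE))
  expect_silent(integrate_risk(NA, FALSE, TRUE))
  expect_error(integrate_risk("intermediate", FALSE, FALSE), "very_low")
})

test_that("route tallies reproduce the published cohort composition", {
  # inputs from the reported cohort: 274 masses, 81 above threshold, 36 with
  # shadows and CA-125 below, remainder decided by the radiomic models
  d <- integrate_risk(
    radiomic = c(rep(NA, 81 + 36), rep("very_low", 157)),
    shadow_present = c(rep(FALSE, 81), rep(TRUE, 36), rep(FALSE, 157)),
    above = c(rep(TRUE, 81), rep(FALSE, 36 + 157))
  )
  rc <- route_counts(d)
  expect_equal(rc$n[rc$route == "radiomic"], 157)
  expect_equal(rc$pct[rc$route == "radiomic"], 57)
  expect_equal(rc$n[rc$route == "ca125_override"], 81)
  expect_equal(sum(rc$n), 274)

  all_shadow <- integrate_risk(NA, TRUE, FALSE)
  rc2 <- route_counts(all_shadow)
  expect_equal(rc2$pct[rc2$route == "shadow_override"], 100)

  rc3 <- route_counts(tibble::tibble(route = character(0)))
  expect_identical(rc3$n, c(0L, 0L, 0L))
})
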