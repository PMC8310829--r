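test_that("perfectly separable features give perfect cross-validation", {
  d <- synth_feature_cohort(n_per_type = 16, seed = 2, sep = 20)
  ens <- train_ensemble(d$features, d$manifest,
                        ensemble_config(seed = 3, stability_threshold = 0))
  expect_true(all(ens$cv_report$cv_accuracy == 1))
  expect_true(all(ens$cv_report$cv_sensitivity == 1))
  # memorization check: every training case re-predicted to its own label
  agg <- aggregate_variants(d$features)
  for (i in seq_len(nrow(d$manifest))) {
    pred <- predict_radiomic(ens, agg[agg$case_id == d$manifest$case_id[i], ],
                             d$manifest$mass_type[i])
    expect_identical(pred$risk,
                     ifelse(d$manifest$label[i] == "malignant",
                            "medium_high", "very_low"))
  }
})

test_that("permuted labels drive cross-validated accuracy to chance", {
  d <- synth_feature_cohort(n_per_type = 70, seed = 8, sep = 3,
                            permute_labels = TRUE)
  ens <- train_ensemble(d$features, d$manifest,
                        ensemble_config(seed = 9, stability_threshold = 0))
  for (acc in ens$cv_report$cv_accuracy) {
    expect_gte(acc, 0.35)
    expect_lte(acc, 0.65)
  }
})

test_that("prediction is deterministic and invariant to column order", {
  d <- synth_feature_cohort(n_per_type = 10, seed = 4, sep = 5)
  ens <- train_ensemble(d$features, d$manifest,
                        ensemble_config(seed = 1, stability_threshold = 0))
  agg <- aggregate_variants(d$features)
  p1 <- predict_radiomic(ens, agg, "solid")
  p2 <- predict_radiomic(ens, agg, "solid")
  expect_identical(p1, p2)
  shuffled <- agg[, c("case_id", rev(setdiff(names(agg), "case_id")))]
  p3 <- predict_radiomic(ens, shuffled, "solid")
  expect_equal(p1$score, p3$score)

  expect_error(predict_radiomic(ens, agg, "papillary"), "mass_type")
  expect_error(predict_radiomic(ens, agg[, 1:2], "solid"), "Missing")
})

test_that("training refuses single-class strata and unlabeled cases", {
  d <- synth_feature_cohort(n_per_type = 6, seed = 5)
  one_class <- d$manifest
  one_class$label[one_class$mass_type == "cystic"] <- "benign"
  expect_error(train_ensemble(d$features, one_class, ensemble_config()),
               "cystic")
  unl <- d$manifest; unl$label[3] <- NA
  expect_error(train_ensemble(d$features, unl, ensemble_config()), "label")
})

test_that("a serialized ensemble round-trips and re-predicts identically", {
  d <- synth_feature_cohort(n_per_type = 34, seed = 6, sep = 2.5)
  ens <- train_ensemble(d$features, d$manifest,
                        ensemble_config(seed = 2, stability_threshold = 0))
  path <- withr::local_tempfile(fileext = ".json")
  write_ensemble(ens, path)
  back <- read_ensemble(path)
  expect_identical(as.character(back$models$solid$panel),
                   as.character(ens$models$solid$panel))
  agg <- aggregate_variants(d$features)   # 102 cases across types
  for (mt in c("solid", "cystic", "mixed")) {
    p0 <- predict_radiomic(ens, agg, mt)
    p1 <- predict_radiomic(back, agg, mt)
    expect_identical(p0$risk, p1$risk)
    expect_equal(p0$score, p1$score, tolerance = 1e-12)
  }
})

test_that("the logistic alternative trains through the same surface", {
  d <- synth_feature_cohort(n_per_type = 16, seed = 12, sep = 8)
  ens <- train_ensemble(d$features, d$manifest,
                        ensemble_config(classifier = "logistic", seed = 3,
                                        stability_threshold = 0))
  expect_true(all(ens$cv_report$cv_accuracy >= 0.9))
})

test_that("tidy and glance expose weights and CV summaries", {
  d <- synth_feature_cohort(n_per_type = 8, seed = 13, sep = 6)
  ens <- train_ensemble(d$features, d$manifest,
                        ensemble_config(seed = 4, stability_threshold = 0))
  td <- tidy(ens)
  expect_setequal(unique(td$mass_type), c("solid", "cystic", "mixed"))
  expect_true(all(c("feature", "weight") %in% names(td)))
  gl <- glance(ens)
  expect_equal(nrow(gl), 3)
  expect_true("cv_sensitivity" %in% names(gl))
})
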