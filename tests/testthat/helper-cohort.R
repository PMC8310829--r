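# Shared fixtures built once per test run and reused across files.

.fixture_env <- new.env(parent = emptyenv())

# Purely tabular synthetic feature cohort for the model tests (no images):
# one informative feature plus noise, per mass type.
synth_feature_cohort <- function(n_per_type = 20, n_variants = 2, seed = 1,
                                 sep = 3, permute_labels = FALSE) {
  withr::with_seed(seed, {
    rows <- list(); man <- list()
    i <- 0
    for (mt in c("solid", "cystic", "mixed")) {
      for (k in seq_len(n_per_type)) {
        i <- i + 1
        label <- if (k <= n_per_type / 2) "malignant" else "benign"
        id <- sprintf("s_%03d", i)
        mu <- if (label == "malignant") sep else 0
        for (v in seq_len(n_variants)) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            case_id = id, variant = v,
            f_signal = mu + rnorm(1, sd = 0.5),
            f_signal2 = mu * 0.5 + rnorm(1, sd = 0.5),
            f_noise = rnorm(1)
          )
        }
        man[[length(man) + 1]] <- tibble::tibble(
          case_id = id, mass_type = mt, shadow = FALSE,
          ca125 = 10, menopausal = "post", label = label
        )
      }
    }
    manifest <- dplyr::bind_rows(man)
    if (permute_labels) manifest$label <- sample(manifest$label)
    list(features = dplyr::bind_rows(rows), manifest = manifest)
  })
}

# The full synthetic study: train n = 300 / test n = 100 at prevalence 0.5,
# five contour variants per case, shared across the end-to-end checks.
acceptance_study <- function() {
  if (!is.null(.fixture_env$study)) return(.fixture_env$study)
  extract_cohort <- function(coh, seed_base) {
    dplyr::bind_rows(lapply(seq_along(coh$cases), function(i) {
      cs <- coh$cases[[i]]
      extract_case_features(cs$frame, cs$annotation$contour,
                            cs$annotation$mass_type,
                            perturbation_config(5, seed = seed_base + i))
    }))
  }
  train <- generate_cohort(300, prevalence = 0.5, seed = 2024)
  test <- generate_cohort(100, prevalence = 0.5, seed = 2025)
  feats_train <- extract_cohort(train, 10000)
  feats_test <- extract_cohort(test, 20000)
  ens <- train_ensemble(feats_train, train$manifest, ensemble_config(seed = 7))
  .fixture_env$study <- list(
    train_manifest = train$manifest, test = test,
    feats_train = feats_train, feats_test = feats_test, ensemble = ens
  )
  .fixture_env$study
}

# One small trained image-based ensemble shared by the expensive tests.
trained_phantom_fixture <- function() {
  if (!is.null(.fixture_env$trained)) return(.fixture_env$trained)
  coh <- generate_cohort(48, prevalence = 0.5, seed = 301)
  feats <- dplyr::bind_rows(lapply(coh$cases, function(cs) {
    extract_case_features(cs$frame, cs$annotation$contour,
                          cs$annotation$mass_type,
                          perturbation_config(4, seed = cs$spec$seed))
  }))
  ens <- train_ensemble(feats, coh$manifest, ensemble_config(seed = 7))
  .fixture_env$trained <- list(cohort = coh, features = feats, ensemble = ens)
  .fixture_env$trained
}
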