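# File-level pipeline stages behind the command-line interface. Each stage
# reads and writes only the documented formats (DICOM/PNG frames, CSV
# contours/manifests/feature tables, JSON panels/models) and never mutates
# its inputs.

#' Simulate a phantom cohort to disk
#'
#' @param out_dir output directory for frames, contours and `manifest.csv`.
#' @param n cohort size.
#' @param prevalence,mix,seed forwarded to [generate_cohort()].
#' @param format `"dcm"` or `"png"` frames.
#' @param ... further arguments to [generate_cohort()].
#' @return the manifest path, invisibly.
#' @export
pipeline_simulate <- function(out_dir, n, prevalence = 0.515,
                              mix = c(solid = 93, cystic = 67, mixed = 79) / 239,
                              seed = 1L, format = "dcm", ...) {
  cohort <- generate_cohort(n, prevalence = prevalence, mix = mix,
                            seed = seed, ...)
  write_cohort(cohort, out_dir, format = format)
}

#' Extract per-variant features for every case in a manifest
#'
#' @param manifest_path cohort manifest CSV (with `image_path`,
#'   `contour_path`).
#' @param out_path output feature-table CSV (one row per case x variant).
#' @param perturb a [perturbation_config()]; each case uses a seed derived
#'   from `perturb$seed` and its row index so extraction is reproducible
#'   case by case.
#' @param disc a [discretization_config()].
#' @param distances GLCM distances.
#' @return the feature table, invisibly (also written to `out_path`).
#' @export
pipeline_extract <- function(manifest_path, out_path,
                             perturb = perturbation_config(seed = 1L),
                             disc = discretization_config(),
                             distances = c(1L, 2L, 4L)) {
  manifest <- read_manifest(manifest_path)
  rows <- purrr::map(seq_len(nrow(manifest)), function(i) {
    frame <- read_frame(manifest$image_path[i],
                        case_id = manifest$case_id[i])
    contour <- read_contour(manifest$contour_path[i])
    cfg <- perturb
    cfg$seed <- derive_seed(perturb$seed %||% 0L, i)
    extract_case_features(frame, contour, manifest$mass_type[i],
                          cfg = cfg, disc_cfg = disc, distances = distances)
  })
  features <- dplyr::bind_rows(rows)
  readr::write_csv(features, out_path)
  invisible(features)
}

#' Stability selection per mass type
#'
#' @param features_path per-variant feature CSV from [pipeline_extract()].
#' @param manifest_path matching manifest CSV.
#' @param out_dir directory for `panel_<type>.json` files and
#'   `stability_<type>.csv` reports.
#' @param threshold ICC selection threshold.
#' @return named list of panels, invisibly.
#' @export
pipeline_select <- function(features_path, manifest_path, out_dir,
                            threshold = 0.75) {
  features <- readr::read_csv(features_path, show_col_types = FALSE,
                              progress = FALSE)
  manifest <- read_manifest(manifest_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  panels <- list()
  for (mt in c("solid", "cystic", "mixed")) {
    ids <- manifest$case_id[manifest$mass_type == mt]
    sub <- features[features$case_id %in% ids, , drop = FALSE]
    sub <- sub[, colSums(is.na(sub)) == 0, drop = FALSE]  # type-specific families
    report <- feature_stability(sub, threshold = threshold)
    readr::write_csv(report, file.path(out_dir, sprintf("stability_%s.csv", mt)))
    panels[[mt]] <- select_panel(report, mt)
    write_panel(panels[[mt]], file.path(out_dir, sprintf("panel_%s.json", mt)))
  }
  invisible(panels)
}

#' Train the risk ensemble from extracted features
#'
#' @param features_path per-variant feature CSV.
#' @param manifest_path labelled manifest CSV.
#' @param model_path output JSON model archive.
#' @param cfg an [ensemble_config()].
#' @return the trained ensemble, invisibly.
#' @export
pipeline_train <- function(features_path, manifest_path, model_path,
                           cfg = ensemble_config()) {
  features <- readr::read_csv(features_path, show_col_types = FALSE,
                              progress = FALSE)
  manifest <- read_manifest(manifest_path, require_label = TRUE)
  ens <- train_ensemble(features, manifest, cfg)
  write_ensemble(ens, model_path)
  readr::write_csv(ens$cv_report,
                   sub("\\.json$", "_cv_report.csv", model_path))
  invisible(ens)
}

#' Apply the DSS to a cohort
#'
#' @param features_path per-variant feature CSV for the cohort.
#' @param manifest_path manifest CSV (label column not required).
#' @param model_path JSON model archive from [pipeline_train()].
#' @param out_path output predictions CSV, one row per case.
#' @param thresholds a [dss_thresholds()].
#' @return the predictions tibble, invisibly.
#' @export
pipeline_predict <- function(features_path, manifest_path, model_path,
                             out_path, thresholds = dss_thresholds()) {
  features <- readr::read_csv(features_path, show_col_types = FALSE,
                              progress = FALSE)
  manifest <- read_manifest(manifest_path)
  ens <- read_ensemble(model_path)
  agg <- aggregate_variants(features)
  preds <- dss_predict(manifest, agg, ens, thresholds = thresholds)
  readr::write_csv(preds, out_path)
  invisible(preds)
}

#' Evaluate predictions against histology labels
#'
#' @param predictions_path predictions CSV from [pipeline_predict()].
#' @param manifest_path labelled manifest CSV.
#' @param out_path output metrics CSV (metric, ratio, percent, CI bounds).
#' @return the metrics tibble, invisibly.
#' @export
pipeline_evaluate <- function(predictions_path, manifest_path, out_path) {
  preds <- readr::read_csv(predictions_path, show_col_types = FALSE,
                           progress = FALSE)
  manifest <- read_manifest(manifest_path, require_label = TRUE)
  labels <- manifest$label[match(preds$case_id, manifest$case_id)]
  metrics <- evaluate_predictions(preds, labels)
  readr::write_csv(metrics, out_path)
  invisible(metrics)
}

#' Run the full pipeline from a configuration list or YAML file
#'
#' simulate -> extract -> select -> train -> predict -> evaluate, writing
#' every artifact plus the effective configuration (and its hash) into
#' `run_dir`. With the same seeds, a re-run reproduces every output file.
#'
#' @param config named list or path to a YAML file; recognized fields:
#'   `run_dir`, `seed`, `n_train`, `n_test`, `prevalence`, `n_variants`,
#'   `amplitude_frac`, `smoothness`, `n_bins`, `stability_threshold`,
#'   `specificity_floor`, `threshold_pre`, `threshold_post`, `format`.
#' @return list with paths and the final metrics tibble.
#' @export
pipeline_run_all <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cf <- utils::modifyList(list(
    run_dir = "dss_run", seed = 1L, n_train = 120, n_test = 40,
    prevalence = 0.515, n_variants = 5, amplitude_frac = 0.05,
    smoothness = 6, n_bins = 64, stability_threshold = 0.75,
    specificity_floor = 0.90, threshold_pre = 200, threshold_post = 71,
    format = "dcm", image_size = c(128, 128)
  ), config)
  dir.create(cf$run_dir, recursive = TRUE, showWarnings = FALSE)
  eff <- file.path(cf$run_dir, "config.yaml")
  yaml::write_yaml(cf, eff)
  cfg_hash <- sum(utf8ToInt(paste(deparse(cf), collapse = "")))
  writeLines(sprintf("adnexdss %s | config hash %d | seed %d",
                     as.character(utils::packageVersion("adnexdss")),
                     cfg_hash, cf$seed),
             file.path(cf$run_dir, "run.log"))

  train_dir <- file.path(cf$run_dir, "train")
  test_dir <- file.path(cf$run_dir, "test")
  man_train <- pipeline_simulate(train_dir, cf$n_train, cf$prevalence,
                                 seed = derive_seed(cf$seed, 1),
                                 format = cf$format,
                                 image_size = cf$image_size)
  man_test <- pipeline_simulate(test_dir, cf$n_test, cf$prevalence,
                                seed = derive_seed(cf$seed, 2),
                                format = cf$format,
                                image_size = cf$image_size)
  perturb <- perturbation_config(cf$n_variants, cf$amplitude_frac,
                                 cf$smoothness, seed = derive_seed(cf$seed, 3))
  disc <- discretization_config(cf$n_bins)
  feat_train <- file.path(cf$run_dir, "features_train.csv")
  feat_test <- file.path(cf$run_dir, "features_test.csv")
  pipeline_extract(man_train, feat_train, perturb, disc)
  perturb_test <- perturb
  perturb_test$seed <- derive_seed(cf$seed, 4)
  pipeline_extract(man_test, feat_test, perturb_test, disc)
  pipeline_select(feat_train, man_train, file.path(cf$run_dir, "panels"),
                  threshold = cf$stability_threshold)
  model_path <- file.path(cf$run_dir, "ensemble.json")
  pipeline_train(feat_train, man_train, model_path,
                 ensemble_config(specificity_floor = cf$specificity_floor,
                                 stability_threshold = cf$stability_threshold,
                                 seed = derive_seed(cf$seed, 5)))
  pred_path <- file.path(cf$run_dir, "predictions_test.csv")
  thr <- dss_thresholds(ca125_post = cf$threshold_post,
                        ca125_pre = cf$threshold_pre)
  preds <- pipeline_predict(feat_test, man_test, model_path, pred_path, thr)
  metrics_path <- file.path(cf$run_dir, "metrics_test.csv")
  metrics <- pipeline_evaluate(pred_path, man_test, metrics_path)
  list(config = cf, manifest_train = man_train, manifest_test = man_test,
       model_path = model_path, predictions_path = pred_path,
       predictions = preds, metrics_path = metrics_path, metrics = metrics)
}
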