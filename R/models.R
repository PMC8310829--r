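# The ensemble of three echotexture-specific risk classifiers.

#' Training configuration for the risk ensemble
#'
#' @param classifier `"svm_linear"` (default), `"logistic"` or
#'   `"random_forest"`-style are selected by this token; only the linear SVM
#'   and logistic options are implemented, matching small-n tabular
#'   radiomics practice.
#' @param cost SVM cost parameter.
#' @param k_folds stratified cross-validation folds (default 10; reduced
#'   automatically when a class has fewer cases than folds).
#' @param specificity_floor the operating threshold on the decision score is
#'   chosen to maximize sensitivity subject to out-of-fold specificity at or
#'   above this floor; the 0.90 default keeps radiomic false positives low
#'   (the CA-125 override already trades some specificity for sensitivity
#'   downstream).
#' @param stability_threshold ICC threshold for panel selection.
#' @param seed integer seed controlling fold assignment.
#' @return list of class `ensemble_config`.
#' @export
ensemble_config <- function(classifier = c("svm_linear", "logistic"),
                            cost = 1, k_folds = 10,
                            specificity_floor = 0.90,
                            stability_threshold = 0.75, seed = 1L) {
  classifier <- match.arg(classifier)
  structure(list(classifier = classifier, cost = cost,
                 k_folds = as.integer(k_folds),
                 specificity_floor = specificity_floor,
                 stability_threshold = stability_threshold,
                 seed = as.integer(seed)),
            class = "ensemble_config")
}

# Stratified fold assignment: shuffled within class, folds as balanced as
# the class sizes allow.
.stratified_folds <- function(labels, k, seed) {
  withr::with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

# Fit one linear model on standardized features; returns weight vector and
# intercept so that score = x_std %*% w + b, positive = malignant.
.fit_linear <- function(x, y, cfg) {
  yf <- factor(y, levels = c("benign", "malignant"))
  if (cfg$classifier == "svm_linear") {
    fit <- e1071::svm(x, yf, kernel = "linear", cost = cfg$cost,
                      scale = FALSE)
    w <- drop(t(fit$coefs) %*% fit$SV)
    b <- -fit$rho
    # e1071 orients positive decision values toward the first internal
    # label; flip so positive scores always mean malignant
    if (levels(yf)[fit$labels[1]] == "benign") { w <- -w; b <- -b }
    list(w = w, b = b)
  } else {
    df <- data.frame(x)
    fit <- suppressWarnings(
      stats::glm(yf ~ ., data = df, family = stats::binomial())
    )
    co <- stats::coef(fit)
    co[is.na(co)] <- 0
    list(w = co[-1], b = co[1])
  }
}

.standardize_fit <- function(x) {
  mu <- colMeans(x)
  sigma <- apply(x, 2, sd)
  sigma[sigma < 1e-12] <- 1
  list(mu = mu, sigma = sigma)
}

.standardize_apply <- function(x, sc) {
  sweep(sweep(x, 2, sc$mu, `-`), 2, sc$sigma, `/`)
}

# Pick the operating threshold on pooled out-of-fold scores: maximize
# sensitivity subject to specificity >= floor; fall back to the Youden
# optimum when no threshold reaches the floor.
.choose_threshold <- function(scores, labels, floor) {
  mal <- labels == "malignant"
  cand <- sort(unique(c(scores, 0)))
  cand <- c(cand[1] - 1e-9, (head(cand, -1) + tail(cand, -1)) / 2,
            tail(cand, 1) + 1e-9, 0)
  sens <- vapply(cand, function(t) mean(scores[mal] > t), numeric(1))
  spec <- vapply(cand, function(t) mean(scores[!mal] <= t), numeric(1))
  ok <- spec >= floor
  if (any(ok)) {
    best <- which(ok)[which.max(sens[ok])]
  } else {
    best <- which.max(sens + spec)
  }
  cand[best]
}

#' Train the three-model risk ensemble
#'
#' For each echotexture stratum: select the stable feature panel on that
#' stratum's per-variant feature table, aggregate variants to one row per
#' case, fit a z-score scaler and a linear classifier, estimate stratified
#' k-fold cross-validated performance, refit on all training cases, and set
#' the operating threshold from pooled out-of-fold scores.
#'
#' @param feature_df per-variant feature tibble (columns `case_id`,
#'   `variant`, features) for all training cases.
#' @param manifest training manifest tibble with `case_id`, `mass_type`,
#'   `label`.
#' @param cfg an [ensemble_config()].
#' @return object of class `dss_ensemble`: per-type panels, scalers, linear
#'   weights, thresholds, a cross-validation report tibble, and `oof`, the
#'   pooled out-of-fold radiomic predictions (one row per training case) from
#'   which whole-system cross-validated performance can be assembled with
#'   [integrate_risk()].
#' @export
train_ensemble <- function(feature_df, manifest, cfg = ensemble_config()) {
  manifest <- validate_manifest(manifest)
  if (anyNA(manifest$label)) abort("Training requires a `label` for every case.")
  models <- list()
  cv_rows <- list()
  oof_rows <- list()
  for (mt in c("solid", "cystic", "mixed")) {
    ids <- manifest$case_id[manifest$mass_type == mt]
    sub <- feature_df[feature_df$case_id %in% ids, , drop = FALSE]
    # features absent for this echotexture class (e.g. the solid-subregion
    # family outside mixed masses) arrive as NA columns after row-binding
    sub <- sub[, colSums(is.na(sub)) == 0, drop = FALSE]
    lab_map <- stats::setNames(manifest$label, manifest$case_id)
    agg <- aggregate_variants(sub)
    y <- unname(lab_map[agg$case_id])
    if (length(unique(y)) < 2 || min(table(y)) < 2) {
      abort(sprintf(
        "Stratum '%s' needs at least 2 cases of each class (got %s).",
        mt, paste(names(table(y)), table(y), sep = "=", collapse = ", ")
      ))
    }
    report <- feature_stability(sub, threshold = cfg$stability_threshold)
    panel <- select_panel(report, mt)
    x <- as.matrix(agg[, panel, drop = FALSE])

    k <- max(2L, min(cfg$k_folds, min(table(y))))
    fold <- .stratified_folds(y, k, derive_seed(cfg$seed, match(mt, c(
      "solid", "cystic", "mixed"
    ))))
    oof <- numeric(length(y))
    for (f in seq_len(k)) {
      tr <- fold != f
      sc <- .standardize_fit(x[tr, , drop = FALSE])
      lm_ <- .fit_linear(.standardize_apply(x[tr, , drop = FALSE], sc),
                         y[tr], cfg)
      oof[!tr] <- drop(.standardize_apply(x[!tr, , drop = FALSE], sc) %*%
                         lm_$w) + lm_$b
    }
    thr <- .choose_threshold(oof, y, cfg$specificity_floor)
    pred_cv <- ifelse(oof > thr, "malignant", "benign")
    oof_rows[[mt]] <- tibble::tibble(
      case_id = agg$case_id, mass_type = mt, label = y, oof_score = oof,
      oof_risk = ifelse(oof > thr, "medium_high", "very_low")
    )
    cm <- confusion(ifelse(pred_cv == "malignant", "medium_high", "very_low"),
                    y)
    cv_rows[[mt]] <- tibble::tibble(
      mass_type = mt, n = length(y), n_malignant = sum(y == "malignant"),
      k_folds = k, panel_size = length(panel),
      cv_sensitivity = cm$TP / (cm$TP + cm$FN),
      cv_specificity = cm$TN / (cm$TN + cm$FP),
      cv_accuracy = (cm$TP + cm$TN) / length(y)
    )
    sc <- .standardize_fit(x)
    lm_ <- .fit_linear(.standardize_apply(x, sc), y, cfg)
    models[[mt]] <- list(panel = panel, scaler = sc, w = lm_$w, b = lm_$b,
                         threshold = thr)
  }
  structure(list(models = models, cv_report = dplyr::bind_rows(cv_rows),
                 oof = dplyr::bind_rows(oof_rows),
                 config = cfg, version = "adnexdss-ensemble-1"),
            class = "dss_ensemble")
}

#' Predict the radiomic (image-only) risk class
#'
#' Applies the mass-type-specific model of the ensemble to one aggregated
#' feature vector (or a tibble of them). The feature set must contain the
#' type's full stable panel; nothing is imputed.
#'
#' @param ensemble a [train_ensemble()] result (possibly reloaded via
#'   [read_ensemble()]).
#' @param features named numeric vector, or tibble with one row per case
#'   containing the panel columns.
#' @param mass_type echotexture class selecting the model.
#' @return tibble with `risk` (`"very_low"`/`"medium_high"`) and `score`.
#' @export
predict_radiomic <- function(ensemble, features, mass_type) {
  match_mass_type(mass_type)
  m <- ensemble$models[[mass_type]]
  if (is.null(m)) abort(sprintf("No trained model for mass type '%s'.", mass_type))
  if (is.numeric(features) && !is.matrix(features)) {
    features <- tibble::as_tibble_row(as.list(features))
  }
  missing <- setdiff(m$panel, names(features))
  if (length(missing)) {
    abort(sprintf("Missing stable-panel feature(s) for '%s' model: %s",
                  mass_type, paste(head(missing, 5), collapse = ", ")))
  }
  x <- as.matrix(features[, m$panel, drop = FALSE])
  score <- drop(.standardize_apply(x, m$scaler) %*% m$w) + m$b
  tibble::tibble(
    risk = ifelse(score > m$threshold, "medium_high", "very_low"),
    score = score
  )
}

#' Serialize / restore a trained ensemble
#'
#' The model file is a versioned JSON archive holding, per mass type, the
#' stable panel, scaler parameters, linear weights and operating threshold,
#' plus the training configuration and seed.
#'
#' @param ensemble a `dss_ensemble`.
#' @param path file path.
#' @export
write_ensemble <- function(ensemble, path) {
  ser <- list(
    version = ensemble$version,
    config = unclass(ensemble$config),
    cv_report = ensemble$cv_report,
    models = purrr::map(ensemble$models, function(m) {
      list(panel = as.character(m$panel),
           mu = as.numeric(m$scaler$mu), sigma = as.numeric(m$scaler$sigma),
           w = as.numeric(m$w), b = m$b, threshold = m$threshold)
    })
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  models <- purrr::map(s$models, function(m) {
    list(panel = m$panel,
         scaler = list(mu = stats::setNames(m$mu, m$panel),
                       sigma = stats::setNames(m$sigma, m$panel)),
         w = stats::setNames(m$w, m$panel), b = m$b, threshold = m$threshold)
  })
  structure(list(models = models,
                 cv_report = tibble::as_tibble(s$cv_report),
                 config = structure(as.list(s$config),
                                    class = "ensemble_config"),
                 version = s$version),
            class = "dss_ensemble")
}

#' @export
print.dss_ensemble <- function(x, ...) {
  cat(sprintf("<dss_ensemble> %s (%s, cost %g)\n", x$version,
              x$config$classifier, x$config$cost))
  print(x$cv_report)
  invisible(x)
}
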