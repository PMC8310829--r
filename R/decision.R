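# Rule-based integration of radiomic risk, acoustic shadow, and
# menopause-corrected serum CA-125.

#' CA-125 decision thresholds
#'
#' Menopause-corrected serum CA-125 cut-offs: 71 U/mL for postmenopausal
#' women (double the upper normal level) and 200 U/mL for premenopausal
#' women. The comparison is strict (`>`): "higher than" the threshold.
#'
#' @param ca125_post postmenopausal threshold in U/mL.
#' @param ca125_pre premenopausal threshold in U/mL.
#' @return list of class `dss_thresholds`.
#' @export
dss_thresholds <- function(ca125_post = 71, ca125_pre = 200) {
  if (ca125_post <= 0 || ca125_pre <= 0) abort("Thresholds must be > 0.")
  structure(list(ca125_post = ca125_post, ca125_pre = ca125_pre),
            class = "dss_thresholds")
}

#' Is CA-125 above the menopause-corrected threshold?
#'
#' @param ca125 serum level(s) in U/mL (>= 0).
#' @param menopausal `"pre"`/`"post"`, recycled against `ca125`.
#' @param thresholds a [dss_thresholds()].
#' @return logical vector; strictly above the status-specific threshold.
#' @export
ca125_above <- function(ca125, menopausal, thresholds = dss_thresholds()) {
  if (any(!is.finite(ca125)) || any(ca125 < 0)) {
    abort("`ca125` must be finite and non-negative.")
  }
  match_menopausal(menopausal)
  thr <- ifelse(menopausal == "post", thresholds$ca125_post,
                thresholds$ca125_pre)
  ca125 > thr
}

#' Integrate radiomic risk with shadow and CA-125 rules
#'
#' The three published rules, in precedence order:
#' 1. CA-125 above the menopause-corrected threshold (with or without
#'    shadow): medium-high risk.
#' 2. Otherwise, acoustic shadow present: very low risk.
#' 3. Otherwise: the radiomic model's prediction.
#'
#' The radiomic prediction may be absent (`NA`) on the two override routes;
#' it is required on the radiomic route.
#'
#' @param radiomic `"very_low"`/`"medium_high"` (or `NA` when overridden).
#' @param shadow_present logical.
#' @param above logical, from [ca125_above()].
#' @return tibble with `final` and `route`
#'   (`"ca125_override"`/`"shadow_override"`/`"radiomic"`).
#' @export
integrate_risk <- function(radiomic, shadow_present, above) {
  n <- max(length(radiomic), length(shadow_present), length(above))
  radiomic <- rep_len(as.character(radiomic), n)
  shadow_present <- rep_len(shadow_present, n)
  above <- rep_len(above, n)
  if (!all(radiomic %in% c("very_low", "medium_high") | is.na(radiomic))) {
    abort("`radiomic` must be \"very_low\", \"medium_high\" or NA.")
  }
  need <- !shadow_present & !above
  if (any(need & is.na(radiomic))) {
    abort("Radiomic prediction is required when neither override applies.")
  }
  route <- dplyr::case_when(
    above ~ "ca125_override",
    shadow_present ~ "shadow_override",
    TRUE ~ "radiomic"
  )
  final <- dplyr::case_when(
    above ~ "medium_high",
    shadow_present ~ "very_low",
    TRUE ~ radiomic
  )
  tibble::tibble(final = final, route = route)
}

#' Tally decision routes
#'
#' @param decisions tibble from [integrate_risk()] (column `route`).
#' @return tibble with one row per route: `route`, `n`, `pct` (percent of
#'   total, rounded half-up to the nearest integer).
#' @export
route_counts <- function(decisions) {
  routes <- c("ca125_override", "shadow_override", "radiomic")
  n_tot <- nrow(decisions)
  counts <- vapply(routes, function(r) sum(decisions$route == r), integer(1),
                   USE.NAMES = FALSE)
  tibble::tibble(
    route = routes,
    n = counts,
    pct = if (n_tot > 0) round_half_up(100 * counts / n_tot) else rep(0, 3)
  )
}

#' Cross-validated performance of the full decision system
#'
#' Combines the ensemble's out-of-fold radiomic predictions with the shadow
#' and CA-125 rules, so every training case is scored by a model that never
#' saw it, then tallies diagnostic metrics against the histology labels.
#'
#' @param ensemble a freshly trained [train_ensemble()] object (its `oof`
#'   table is not serialized).
#' @param manifest the training manifest (`case_id`, `shadow`, `ca125`,
#'   `menopausal`, `label`).
#' @param thresholds a [dss_thresholds()].
#' @return list with `decisions` (per-case tibble) and `metrics`
#'   (a [dss_metrics()] tibble).
#' @export
dss_cross_validate <- function(ensemble, manifest,
                               thresholds = dss_thresholds()) {
  if (is.null(ensemble$oof)) {
    abort("Ensemble carries no out-of-fold table (was it reloaded from disk?).")
  }
  manifest <- validate_manifest(manifest)
  df <- dplyr::inner_join(ensemble$oof, manifest, by = "case_id",
                          suffix = c("", ".manifest"))
  above <- ca125_above(df$ca125, df$menopausal, thresholds)
  routed <- integrate_risk(df$oof_risk, df$shadow, above)
  decisions <- dplyr::bind_cols(df[, c("case_id", "mass_type", "label",
                                       "oof_risk")], routed)
  list(decisions = decisions,
       metrics = evaluate_predictions(decisions$final, decisions$label))
}

#' Apply the full decision support system to a cohort
#'
#' Computes (and logs) the radiomic prediction for every case, then applies
#' the shadow and CA-125 rules; overridden cases keep their radiomic
#' prediction for audit but the final class comes from the rules.
#'
#' @param manifest validated manifest tibble (`case_id`, `mass_type`,
#'   `shadow`, `ca125`, `menopausal`).
#' @param features aggregated one-row-per-case feature tibble.
#' @param ensemble a trained [train_ensemble()] object.
#' @param thresholds a [dss_thresholds()].
#' @return tibble: `case_id`, `mass_type`, `shadow`, `ca125`, `menopausal`,
#'   `radiomic_risk`, `radiomic_score`, `route`, `final_risk`.
#' @export
dss_predict <- function(manifest, features, ensemble,
                        thresholds = dss_thresholds()) {
  manifest <- validate_manifest(manifest)
  feats <- features[match(manifest$case_id, features$case_id), , drop = FALSE]
  if (anyNA(feats$case_id)) {
    abort("`features` must contain one aggregated row per manifest case.")
  }
  rad <- purrr::map2_dfr(seq_len(nrow(manifest)), manifest$mass_type,
    function(i, mt) predict_radiomic(ensemble, feats[i, , drop = FALSE], mt))
  above <- ca125_above(manifest$ca125, manifest$menopausal, thresholds)
  routed <- integrate_risk(rad$risk, manifest$shadow, above)
  tibble::tibble(
    case_id = manifest$case_id,
    mass_type = manifest$mass_type,
    shadow = manifest$shadow,
    ca125 = manifest$ca125,
    menopausal = manifest$menopausal,
    radiomic_risk = rad$risk,
    radiomic_score = rad$score,
    route = routed$route,
    final_risk = routed$final
  )
}
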