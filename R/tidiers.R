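# broom-style tidiers for fitted and evaluated objects.

#' Tidy a trained risk ensemble
#'
#' One row per (mass type, panel feature) with the standardized linear
#' weight; large absolute weights mark the features driving that model.
#'
#' @param x a `dss_ensemble`.
#' @param ... unused.
#' @return tibble: `mass_type`, `feature`, `weight`.
#' @exportS3Method generics::tidy
tidy.dss_ensemble <- function(x, ...) {
  purrr::imap_dfr(x$models, function(m, mt) {
    tibble::tibble(mass_type = mt, feature = m$panel,
                   weight = unname(m$w))
  })
}

#' Glance at a trained risk ensemble
#'
#' @param x a `dss_ensemble`.
#' @param ... unused.
#' @return the per-type cross-validation report with the configuration
#'   columns appended.
#' @exportS3Method generics::glance
glance.dss_ensemble <- function(x, ...) {
  x$cv_report |>
    dplyr::mutate(classifier = x$config$classifier,
                  specificity_floor = x$config$specificity_floor)
}

#' Tidy a stability report
#'
#' @param x a `stability_report`.
#' @param ... unused.
#' @return the underlying tibble ordered by descending ICC.
#' @exportS3Method generics::tidy
tidy.stability_report <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::arrange(dplyr::desc(.data$icc), .data$feature)
}

#' Glance at a stability report
#'
#' @param x a `stability_report`.
#' @param ... unused.
#' @return one-row tibble: feature counts, threshold, median ICC.
#' @exportS3Method generics::glance
glance.stability_report <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x),
    n_selected = sum(x$selected),
    n_degenerate = sum(x$degenerate),
    threshold = x$threshold[1],
    median_icc = median(x$icc, na.rm = TRUE)
  )
}

#' Tidy diagnostic metrics
#'
#' @param x a `dss_metrics` tibble.
#' @param ... unused.
#' @return tibble with `metric`, `ratio` (e.g. `"122/123"`), `percent`,
#'   `ci_low_pct`, `ci_high_pct` — the shape diagnostic-accuracy tables are
#'   reported in.
#' @exportS3Method generics::tidy
tidy.dss_metrics <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::mutate(ratio = sprintf("%d/%d", .data$numerator,
                                  .data$denominator)) |>
    dplyr::select("metric", "ratio", "percent", "ci_low_pct", "ci_high_pct")
}
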