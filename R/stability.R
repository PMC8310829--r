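# Feature stability under contour perturbation: one-way intraclass
# correlation across contour variants, and panel selection.

#' One-way intraclass correlation ICC(1,1)
#'
#' Treats masses as subjects and contour variants as repeated raters:
#' `ICC = (MS_between - MS_within) / (MS_between + (k - 1) * MS_within)`,
#' clipped to `[0, 1]`. With unequal variant counts per mass, `k` is the
#' harmonic mean count (with a warning). Zero total variance is degenerate
#' (`NA` score).
#'
#' @param values numeric vector of feature values.
#' @param subject factor/vector identifying the mass of each value.
#' @return list with `icc` (or `NA`), `k`, `degenerate`.
#' @export
icc_oneway <- function(values, subject) {
  subject <- factor(subject)
  ni <- table(subject)
  if (nlevels(subject) < 2 || any(ni < 2)) {
    abort("ICC needs >= 2 masses with >= 2 variants each.")
  }
  if (length(unique(ni)) > 1) {
    warn("Unequal variant counts; using harmonic-mean k.")
  }
  k <- length(ni) / sum(1 / as.numeric(ni))
  if (var(values) < .Machine$double.eps) {
    return(list(icc = NA_real_, k = k, degenerate = TRUE))
  }
  gm <- mean(values)
  means <- tapply(values, subject, mean)
  ssb <- sum(as.numeric(ni) * (means - gm)^2)
  ssw <- sum((values - means[subject])^2)
  n <- nlevels(subject)
  msb <- ssb / (n - 1)
  msw <- ssw / (length(values) - n)
  icc <- (msb - msw) / (msb + (k - 1) * msw)
  list(icc = min(max(icc, 0), 1), k = k, degenerate = FALSE)
}

#' Score feature stability under contour perturbation
#'
#' @param feature_df tibble with columns `case_id`, `variant`, and one column
#'   per feature (from [extract_case_features()] over >= 2 masses).
#' @param threshold ICC selection threshold; the default 0.75 is the usual
#'   radiomics robustness criterion.
#' @return tibble of class `stability_report`: `feature`, `icc`,
#'   `degenerate`, `selected`, `threshold`.
#' @export
feature_stability <- function(feature_df, threshold = 0.75) {
  stopifnot(all(c("case_id", "variant") %in% names(feature_df)))
  feats <- setdiff(names(feature_df)[vapply(feature_df, is.numeric, logical(1))],
                   "variant")
  subject <- feature_df$case_id
  rows <- purrr::map(sort(feats), function(f) {
    r <- icc_oneway(feature_df[[f]], subject)
    tibble::tibble(feature = f, icc = r$icc, degenerate = r$degenerate)
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(
      selected = !.data$degenerate & .data$icc >= .env$threshold,
      threshold = .env$threshold
    )
  class(out) <- c("stability_report", class(out))
  out
}

#' Select the stable feature panel for a mass type
#'
#' @param report a [feature_stability()] report computed on training masses
#'   of one echotexture type.
#' @param mass_type the type the panel belongs to (stored as an attribute).
#' @param threshold optional override of the report's threshold.
#' @return character vector of feature names ordered by descending ICC
#'   (feature name as tie-break), with attributes `mass_type`, `threshold`,
#'   `icc`.
#' @export
select_panel <- function(report, mass_type, threshold = NULL) {
  match_mass_type(mass_type)
  thr <- threshold %||% report$threshold[1]
  sel <- report |>
    dplyr::filter(!.data$degenerate, .data$icc >= .env$thr) |>
    dplyr::arrange(dplyr::desc(.data$icc), .data$feature)
  if (nrow(sel) == 0) {
    abort(sprintf(
      "No feature reaches ICC >= %.2f for %s masses; lower the stability threshold.",
      thr, mass_type
    ))
  }
  structure(sel$feature, mass_type = mass_type, threshold = thr,
            icc = stats::setNames(sel$icc, sel$feature))
}

#' Write / read a stable-feature panel file
#'
#' Panels are persisted as JSON: feature names, ICC scores, the threshold
#' used, and the mass type.
#'
#' @param panel result of [select_panel()].
#' @param path output path.
#' @export
write_panel <- function(panel, path) {
  jsonlite::write_json(
    list(mass_type = attr(panel, "mass_type"),
         threshold = attr(panel, "threshold"),
         features = as.character(panel),
         icc = as.numeric(attr(panel, "icc"))),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(p$features, mass_type = p$mass_type, threshold = p$threshold,
            icc = stats::setNames(p$icc, p$features))
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %d features, threshold %.2f, %d selected, %d degenerate\n",
              nrow(x), x$threshold[1], sum(x$selected), sum(x$degenerate)))
  NextMethod()
}
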