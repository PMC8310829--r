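# Diagnostic accuracy versus the histology reference, with exact binomial
# confidence intervals.

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Computed from beta-distribution quantiles:
#' `low = qbeta(alpha/2, x, n - x + 1)`, `high = qbeta(1 - alpha/2, x + 1,
#' n - x)`, with `low = 0` at `x = 0` and `high = 1` at `x = n` (where the
#' lower bound reduces to `(alpha/2)^(1/n)`).
#'
#' @param x successes, `0 <= x <= n`.
#' @param n trials, `>= 1`.
#' @param confidence confidence level (default 0.95).
#' @return named numeric `c(low, high)` on the proportion scale.
#' @export
clopper_pearson <- function(x, n, confidence = 0.95) {
  if (n < 1 || x < 0 || x > n) abort("Require 0 <= x <= n and n >= 1.")
  alpha <- 1 - confidence
  low <- if (x == 0) 0 else qbeta(alpha / 2, x, n - x + 1)
  high <- if (x == n) 1 else qbeta(1 - alpha / 2, x + 1, n - x)
  c(low = low, high = high)
}

#' Confusion counts for binary risk predictions
#'
#' The positive pairing is medium-high prediction with malignant histology.
#'
#' @param predictions `"medium_high"`/`"very_low"` (or
#'   `"malignant"`/`"benign"`).
#' @param labels `"malignant"`/`"benign"` reference.
#' @return list of class `confusion_counts` with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(predictions, labels) {
  if (length(predictions) != length(labels)) {
    abort("`predictions` and `labels` must have equal length.")
  }
  pos_pred <- predictions %in% c("medium_high", "malignant")
  neg_pred <- predictions %in% c("very_low", "benign")
  if (!all(pos_pred | neg_pred)) abort("Unrecognized prediction value.")
  if (!all(labels %in% c("malignant", "benign"))) {
    abort("Labels must be \"malignant\" or \"benign\".")
  }
  mal <- labels == "malignant"
  structure(list(
    TP = sum(pos_pred & mal), FP = sum(pos_pred & !mal),
    TN = sum(neg_pred & !mal), FN = sum(neg_pred & mal)
  ), class = "confusion_counts")
}

#' @rdname confusion
#' @param TP,FP,TN,FN non-negative integer counts.
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  counts <- c(TP, FP, TN, FN)
  if (any(counts < 0) || sum(counts) == 0) {
    abort("Counts must be non-negative with a positive total.")
  }
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN),
            class = "confusion_counts")
}

#' Diagnostic-accuracy metrics with exact binomial CIs
#'
#' Sensitivity, specificity, accuracy, PPV and NPV from a 2x2 table, each
#' with its numerator/denominator, the percentage rounded half-up to one
#' decimal, and the exact Clopper-Pearson 95% interval. Metrics with a zero
#' denominator are returned as undefined (`NA`) without blocking the others.
#'
#' @param counts a [confusion()] / [confusion_counts()] object.
#' @param confidence confidence level.
#' @return tibble of class `dss_metrics`: `metric`, `numerator`,
#'   `denominator`, `estimate` (fraction), `percent` (1 d.p.), `ci_low`,
#'   `ci_high` (fractions), `ci_low_pct`, `ci_high_pct` (1 d.p.).
#' @export
dss_metrics <- function(counts, confidence = 0.95) {
  stopifnot(inherits(counts, "confusion_counts"))
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  defs <- list(
    sensitivity = c(TP, TP + FN),
    specificity = c(TN, TN + FP),
    accuracy = c(TP + TN, TP + FP + TN + FN),
    ppv = c(TP, TP + FP),
    npv = c(TN, TN + FN)
  )
  rows <- purrr::imap(defs, function(d, nm) {
    x <- d[1]; n <- d[2]
    if (n == 0) {
      return(tibble::tibble(metric = nm, numerator = x, denominator = n,
                            estimate = NA_real_, percent = NA_real_,
                            ci_low = NA_real_, ci_high = NA_real_,
                            ci_low_pct = NA_real_, ci_high_pct = NA_real_))
    }
    ci <- clopper_pearson(x, n, confidence)
    tibble::tibble(
      metric = nm, numerator = x, denominator = n,
      estimate = x / n,
      percent = round_half_up(100 * x / n, 1),
      ci_low = ci[["low"]], ci_high = ci[["high"]],
      ci_low_pct = round_half_up(100 * ci[["low"]], 1),
      ci_high_pct = round_half_up(100 * ci[["high"]], 1)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("dss_metrics", class(out))
  out
}

#' Evaluate final risk predictions against histology
#'
#' @param predictions tibble from [dss_predict()] (column `final_risk`), or
#'   a character vector of risk classes.
#' @param labels histology reference (`"malignant"`/`"benign"`).
#' @param confidence confidence level.
#' @return a [dss_metrics()] tibble.
#' @export
evaluate_predictions <- function(predictions, labels, confidence = 0.95) {
  pred <- if (is.data.frame(predictions)) predictions$final_risk else predictions
  dss_metrics(confusion(pred, labels), confidence = confidence)
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d FP=%d TN=%d FN=%d (n=%d)\n",
              x$TP, x$FP, x$TN, x$FN, x$TP + x$FP + x$TN + x$FN))
  invisible(x)
}
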