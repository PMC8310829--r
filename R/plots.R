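# ggplot2 displays for frames, stability reports, metrics and routing.

#' Plot an ultrasound frame with optional contour overlay
#'
#' @param object an [om_frame()].
#' @param contour optional contour matrix to overlay.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.om_frame <- function(object, contour = NULL, ...) {
  df <- tidyr::expand_grid(y = seq_len(nrow(object$pixels)) - 1,
                           x = seq_len(ncol(object$pixels)) - 1)
  df$intensity <- as.vector(t(object$pixels))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                        fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = object$case_id, x = NULL, y = NULL) +
    ggplot2::theme_void()
  if (!is.null(contour)) {
    cdf <- tibble::tibble(x = contour[, 1], y = contour[, 2])
    p <- p + ggplot2::geom_path(
      data = rbind(cdf, cdf[1, ]),
      mapping = ggplot2::aes(.data$x, .data$y),
      inherit.aes = FALSE, colour = "yellow", linewidth = 0.4
    )
  }
  p
}

#' Plot the ICC distribution of a stability report
#'
#' @param object a `stability_report`.
#' @param ... unused.
#' @return a ggplot histogram with the selection threshold marked.
#' @exportS3Method ggplot2::autoplot
autoplot.stability_report <- function(object, ...) {
  df <- tibble::as_tibble(object) |> dplyr::filter(!.data$degenerate)
  ggplot2::ggplot(df, ggplot2::aes(.data$icc, fill = .data$selected)) +
    ggplot2::geom_histogram(bins = 40, boundary = 0) +
    ggplot2::geom_vline(xintercept = object$threshold[1], linetype = 2) +
    ggplot2::labs(x = "ICC(1,1) across contour variants", y = "features",
                  fill = "selected") +
    ggplot2::theme_minimal()
}

#' Plot diagnostic metrics with exact binomial CIs
#'
#' @param object a `dss_metrics` tibble.
#' @param ... unused.
#' @return a ggplot of point estimates with 95% CI bars.
#' @exportS3Method ggplot2::autoplot
autoplot.dss_metrics <- function(object, ...) {
  df <- tibble::as_tibble(object) |> dplyr::filter(!is.na(.data$estimate))
  ggplot2::ggplot(df, ggplot2::aes(.data$metric, .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v),
                                limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "estimate (95% exact CI)") +
    ggplot2::theme_minimal()
}

#' Plot decision-route composition
#'
#' @param decisions tibble from [dss_predict()] or [integrate_risk()].
#' @return a ggplot bar chart of routing counts.
#' @export
plot_routes <- function(decisions) {
  rc <- route_counts(decisions)
  ggplot2::ggplot(rc, ggplot2::aes(.data$route, .data$n)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%d%%", .data$pct)),
                       vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "cases") +
    ggplot2::theme_minimal()
}
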