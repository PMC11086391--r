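#' Residual plot for an evaluation report
#'
#' True angle on the x-axis, residual (actual - predicted) on the y-axis,
#' the standard regression diagnostic for angle-estimation models.
#'
#' @param report an [eval_report].
#' @param truth true angles matching `report$residuals` (only needed if the
#'   report was built without storing them; defaults to reconstructing from
#'   the per-angle summary is not possible, so pass the test table's
#'   `true_angle_deg`).
#' @return a ggplot object.
#' @export
plot_residuals <- function(report, truth) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_residuals requires ggplot2", call. = FALSE)
  }
  df <- data.frame(truth = truth, residual = report$residuals)
  ggplot2::ggplot(df, ggplot2::aes(x = truth, y = residual)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.25, size = 0.7) +
    ggplot2::labs(x = "true angle (deg)",
                  y = "residual: actual - predicted (deg)",
                  title = report$algorithm)
}

#' Heatmap of the feature/angle correlation matrix
#'
#' @param cm matrix from [feature_correlation_matrix()].
#' @return a ggplot object.
#' @export
plot_correlation_heatmap <- function(cm) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_correlation_heatmap requires ggplot2", call. = FALSE)
  }
  df <- as.data.frame(as.table(cm))
  names(df) <- c("row", "col", "r")
  ggplot2::ggplot(df, ggplot2::aes(x = col, y = row,
                                   fill = r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r")
}
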