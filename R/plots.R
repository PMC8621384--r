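#' Plot the stages of a pipeline result
#'
#' Grayscale panels of the vesselness map, the curvelet-enhanced image and
#' the final binary mask.
#'
#' @param x A `vesselx_result` from [run_pipeline()].
#' @param ... Ignored.
#' @return `x`, invisibly.
#' @export
plot.vesselx_result <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  show <- function(m, title) {
    graphics::image(t(m)[, nrow(m):1], col = gray.colors(256, 0, 1),
                    axes = FALSE, main = title, useRaster = TRUE)
  }
  show(x$vesselness$response, "vesselness")
  show(x$enhanced, "curvelet enhanced")
  show(x$mask, "segmentation")
  invisible(x)
}

#' Bar chart of per-image segmentation metrics
#'
#' @param object A `vesselx_report` from [aggregate_metrics()] or
#'   [evaluate_dataset()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.vesselx_report <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("vesselx: ggplot2 is required for autoplot()", call. = FALSE)
  }
  rows <- object$rows
  long <- do.call(rbind, lapply(
    c("sensitivity", "specificity", "accuracy", "precision"),
    function(m) data.frame(image_id = rows$image_id, metric = m,
                           value = rows[[m]])))
  ggplot2::ggplot(long, ggplot2::aes(x = image_id, y = value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

utils::globalVariables(c("image_id", "value", "metric"))
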