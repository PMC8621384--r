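#' Pixel-level confusion counts against ground truth
#'
#' @param pred,truth 0/1 matrices of identical dimensions.
#' @param fov Optional 0/1 matrix; counts are restricted to pixels inside
#'   it. `NULL` evaluates the whole frame.
#' @return A list of class `confusion_counts` with integers `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
confusion_counts <- function(pred, truth, fov = NULL) {
  if (!all(dim(pred) == dim(truth))) {
    stop("vesselx: prediction and truth dimensions differ", call. = FALSE)
  }
  sel <- if (is.null(fov)) {
    rep(TRUE, length(pred))
  } else {
    if (!all(dim(fov) == dim(pred))) {
      stop("vesselx: field-of-view dimensions differ", call. = FALSE)
    }
    as.vector(fov > 0)
  }
  p <- as.vector(pred > 0)[sel]
  t <- as.vector(truth > 0)[sel]
  structure(list(tp = sum(p & t), fp = sum(p & !t),
                 tn = sum(!p & !t), fn = sum(!p & t)),
            class = "confusion_counts")
}

#' Segmentation metrics from confusion counts
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/(TP+FN+TN+FP)` and precision `TP/(TP+FP)`. A metric with a zero
#' denominator is reported as `NA` (an explicit undefined marker), never
#' silently as 0 or 1.
#'
#' @param counts A `confusion_counts` object, or a list with `tp`, `fp`,
#'   `tn`, `fn`.
#' @param image_id Label for the row. Default `NA`.
#' @return A one-row [tibble::tibble()] with columns `image_id`,
#'   `sensitivity`, `specificity`, `accuracy`, `precision`.
#' @examples
#' metrics(list(tp = 8, fp = 2, tn = 88, fn = 2))
#' @export
metrics <- function(counts, image_id = NA_character_) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  total <- tp + fp + tn + fn
  if (total == 0) {
    stop("vesselx: no evaluated pixels (all-zero counts)", call. = FALSE)
  }
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  tibble::tibble(
    image_id   = as.character(image_id),
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    accuracy    = (tp + tn) / total,
    precision   = ratio(tp, tp + fp))
}

#' Aggregate per-image metric rows into a report
#'
#' Column-wise unweighted arithmetic means over the rows, skipping `NA`
#' (undefined) entries and recording how many were skipped per column.
#'
#' @param rows Tibble/data frame of per-image metric rows as produced by
#'   [metrics()].
#' @return An object of class `vesselx_report`: a list with `rows`, `means`
#'   (one-row tibble labeled `"mean"`), and `n_undefined` (named integer
#'   vector of skipped entries per metric).
#' @export
aggregate_metrics <- function(rows) {
  if (is.null(rows) || nrow(rows) == 0) {
    stop("vesselx: cannot aggregate an empty set of metric rows",
         call. = FALSE)
  }
  cols <- c("sensitivity", "specificity", "accuracy", "precision")
  means <- vapply(cols, function(cl) mean(rows[[cl]], na.rm = TRUE),
                  numeric(1))
  skipped <- vapply(cols, function(cl) sum(is.na(rows[[cl]])), integer(1))
  mean_row <- tibble::tibble(image_id = "mean",
                             sensitivity = means[["sensitivity"]],
                             specificity = means[["specificity"]],
                             accuracy = means[["accuracy"]],
                             precision = means[["precision"]])
  structure(list(rows = tibble::as_tibble(rows), means = mean_row,
                 n_undefined = skipped),
            class = "vesselx_report")
}

#' @export
print.vesselx_report <- function(x, ...) {
  cat("Vessel segmentation report (", nrow(x$rows), " images)\n", sep = "")
  print(x$rows, n = nrow(x$rows))
  cat("column means:\n")
  print(x$means)
  if (any(x$n_undefined > 0)) {
    cat("undefined entries skipped:",
        paste(names(x$n_undefined), x$n_undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write an evaluation report as CSV
#'
#' Per-image rows followed by a final `mean` row, with columns `image_id`,
#' `sensitivity`, `specificity`, `accuracy`, `precision`.
#'
#' @param report A `vesselx_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- rbind(as.data.frame(report$rows), as.data.frame(report$means))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Dice overlap coefficient between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; used internally for phantom recovery checks.
#'
#' @param a,b 0/1 matrices of identical dimensions.
#' @return Numeric in \[0, 1\] (`NaN` when both masks are empty).
#' @export
dice <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  2 * sum(a > 0 & b > 0) / (sum(a > 0) + sum(b > 0))
}

#' Published per-image baseline metrics bundled with the package
#'
#' Per-image sensitivity/specificity/accuracy/precision of mean-C
#' thresholding applied to plain curvelet-enhanced images on the DRIVE
#' (20 test images) and CHASE_DB1 (14 images) sets, as published for this
#' method's baseline. Bundled so report arithmetic (column means) can be
#' exercised without downloading either database.
#'
#' @param dataset `"drive"` or `"chase"`.
#' @return Tibble with `image_id` and the four metric columns.
#' @export
curvelet_baseline_metrics <- function(dataset = c("drive", "chase")) {
  dataset <- match.arg(dataset)
  path <- system.file("extdata",
                      paste0(dataset, "_curvelet_metrics.csv"),
                      package = "vesselx", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, colClasses = c(
    image_id = "character", sensitivity = "numeric",
    specificity = "numeric", accuracy = "numeric", precision = "numeric")))
}
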