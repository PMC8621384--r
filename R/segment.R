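#' Parameters for mean-C thresholding and morphological cleanup
#'
#' A pixel is labeled vessel when it exceeds its local box-filter mean by
#' more than the constant `c`, which is fixed at 0.039 on the \[0, 1\]
#' intensity scale. The mean-filter window `W` scales with image width
#' (13 px for a 565-px-wide image) when left as `NULL`.
#'
#' @param window Odd integer window side length >= 3, or `NULL` to scale
#'   with image width at apply time.
#' @param c Threshold constant in \[0, 1). Default 0.039.
#' @param opening_radius Structuring-disk radius (px) for the morphological
#'   opening of the raw mask. Default 1.
#' @param min_object_px Minimum 8-connected component area kept. Default 30.
#' @return An object of class `threshold_params`.
#' @export
threshold_params <- function(window = NULL, c = 0.039, opening_radius = 1,
                             min_object_px = 30) {
  if (!is.null(window)) {
    stopifnot(window >= 3, window %% 2 == 1)
  }
  stopifnot(c >= 0, c < 1, opening_radius >= 0, min_object_px >= 0)
  structure(list(window = window, c = c,
                 opening_radius = as.integer(opening_radius),
                 min_object_px = as.integer(min_object_px)),
            class = "threshold_params")
}

# Resolve the window size for a given image width: 13 px at width 565,
# scaled proportionally, forced odd and >= 3.
resolve_window <- function(params, width) {
  if (!is.null(params$window)) return(as.integer(params$window))
  w <- round(13 * width / 565)
  w <- max(3L, as.integer(w))
  if (w %% 2L == 0L) w <- w + 1L
  w
}

#' Mean-C adaptive thresholding
#'
#' Convolves the enhanced image with a `W x W` box filter (reflect padding),
#' subtracts the mean image, and labels pixels whose difference strictly
#' exceeds `c` as vessel. Ties are background, and everything outside the
#' field of view is background.
#'
#' @param img 2D numeric matrix in \[0, 1\] (vessels bright).
#' @param params A [threshold_params()] object.
#' @param fov Optional 0/1 field-of-view matrix.
#' @return 0/1 integer matrix.
#' @examples
#' x <- matrix(0, 5, 5); x[3, 3] <- 1
#' mean_c_threshold(x, threshold_params(window = 3))
#' @export
mean_c_threshold <- function(img, params = threshold_params(), fov = NULL) {
  stopifnot(is.matrix(img), all(is.finite(img)))
  w <- resolve_window(params, ncol(img))
  if (w >= min(dim(img))) {
    stop("vesselx: mean-filter window ", w, " too large for image ",
         nrow(img), "x", ncol(img), " (degenerate input)", call. = FALSE)
  }
  k <- rep(1 / w, w)
  m <- conv_separable(img, k, k)
  mask <- (img - m > params$c) * 1L
  if (!is.null(fov)) mask[fov == 0] <- 0L
  mask
}

#' Morphological cleanup of a binary vessel mask
#'
#' Opening with a disk of radius `opening_radius` followed by removal of
#' 8-connected components smaller than `min_object_px`. Anti-extensive
#' (output is a subset of the input) and idempotent.
#'
#' @param mask 0/1 matrix.
#' @param params A [threshold_params()] object.
#' @return 0/1 integer matrix.
#' @export
cleanup <- function(mask, params = threshold_params()) {
  out <- mask * 1L
  if (params$opening_radius > 0 && any(out > 0)) {
    brush <- EBImage::makeBrush(2L * params$opening_radius + 1L, "disc")
    out <- matrix(as.integer(EBImage::opening(out * 1, brush) > 0.5),
                  nrow(mask), ncol(mask))
  }
  if (params$min_object_px > 0 && any(out > 0)) {
    lab <- label_components(out)
    sizes <- tabulate(lab[lab > 0L])
    small <- which(sizes < params$min_object_px)
    if (length(small)) out[lab %in% small] <- 0L
  }
  out
}
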