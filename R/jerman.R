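#' Parameters for the multiscale Jerman vesselness filter
#'
#' The filter responds to elongated (tubular) structures by comparing the two
#' eigenvalues of the scale-normalized image Hessian. `tau` is the cut-off
#' threshold of the eigenvalue regularization: at each scale the
#' larger-magnitude eigenvalue is clamped from below at `tau` times its
#' per-scale maximum, which flattens the response inside vessels of matched
#' scale to a plateau of 1. Lower `tau` (around 0.5) preserves vessel
#' connectivity; values near 1 suppress bifurcations.
#'
#' @param tau Cut-off threshold in (0, 1]. Default 0.5.
#' @param s_min,s_max Smallest and largest detection scale in pixels
#'   (used directly as the Gaussian sigma). Defaults 3 and 16.
#' @param s_step Scale increment in pixels. Default 0.5.
#' @param polarity `"dark-on-bright"` (fundus vessels in the green channel)
#'   or `"bright-on-dark"`.
#' @return An object of class `jerman_params`.
#' @examples
#' jerman_params(tau = 0.5, s_min = 3, s_max = 16)
#' @export
jerman_params <- function(tau = 0.5, s_min = 3, s_max = 16, s_step = 0.5,
                          polarity = c("dark-on-bright", "bright-on-dark")) {
  polarity <- match.arg(polarity)
  stopifnot(tau > 0, tau <= 1, s_min > 0, s_min <= s_max, s_step > 0)
  structure(list(tau = tau, s_min = s_min, s_max = s_max, s_step = s_step,
                 polarity = polarity),
            class = "jerman_params")
}

#' Scale-normalized Hessian of an image
#'
#' Second derivatives of the Gaussian-smoothed image at scale `sigma`,
#' computed by separable correlation with reflect padding and multiplied by
#' `sigma^2` (gamma = 2 normalization), so responses are comparable across
#' scales.
#'
#' @param img 2D numeric matrix.
#' @param sigma Gaussian scale in pixels (> 0).
#' @return A list of class `hessian_field` with matrices `hxx`, `hxy`, `hyy`
#'   (x = column direction, y = row direction) and the `scale`.
#' @export
hessian_at_scale <- function(img, sigma) {
  stopifnot(is.matrix(img), all(is.finite(img)), sigma > 0)
  k <- gaussian_kernels(sigma)
  if (2L * k$radius + 1L > 2L * min(dim(img)) - 1L) {
    stop("vesselx: scale ", sigma, " too large for image of size ",
         nrow(img), "x", ncol(img), " (degenerate input)", call. = FALSE)
  }
  s2 <- sigma^2
  structure(list(
    hxx = s2 * conv_separable(img, k$smooth, k$d2),
    hxy = s2 * conv_separable(img, k$d1, k$d1),
    hyy = s2 * conv_separable(img, k$d2, k$smooth),
    scale = sigma), class = "hessian_field")
}

#' Closed-form eigenvalues of a field of symmetric 2x2 matrices
#'
#' Per-pixel eigenvalues of `[[hxx, hxy], [hxy, hyy]]`, ordered by magnitude
#' `|lam1| <= |lam2|`; exact magnitude ties are ordered ascending by signed
#' value.
#'
#' @param h A `hessian_field` from [hessian_at_scale()].
#' @return A list of class `eigen_field` with matrices `lam1`, `lam2`.
#' @export
eigenvalues_2x2 <- function(h) {
  half_tr <- (h$hxx + h$hyy) / 2
  disc <- sqrt(((h$hxx - h$hyy) / 2)^2 + h$hxy^2)
  ehi <- half_tr + disc   # signed-larger eigenvalue
  elo <- half_tr - disc
  swap <- abs(elo) > abs(ehi)   # ties keep ascending signed order
  lam1 <- ifelse(swap, ehi, elo)
  lam2 <- ifelse(swap, elo, ehi)
  structure(list(lam1 = lam1, lam2 = lam2), class = "eigen_field")
}

#' Cut-off regularization of the larger Hessian eigenvalue
#'
#' With `M` the maximum of `lam2` over the grid at the current scale:
#' values above `tau * M` pass unchanged; positive values at or below the
#' cut are raised to `tau * M`; non-positive values map to 0. If `M` is not
#' positive — up to the floating-point residue a locally constant image
#' leaves in the Hessian (1e-10 on the \[0, 1\] intensity scale) — the
#' whole grid maps to 0.
#'
#' @param lam2 Matrix of larger-magnitude eigenvalues at one scale.
#' @param tau Cut-off threshold in (0, 1].
#' @return Matrix of regularized eigenvalues.
#' @export
regularize_lambda <- function(lam2, tau) {
  stopifnot(tau > 0, tau <= 1)
  m <- max(lam2)
  if (!is.finite(m) || m <= 1e-10) return(array(0, dim(lam2)))
  cut <- tau * m
  out <- lam2
  out[lam2 <= cut & lam2 > 0] <- cut
  out[lam2 <= 0] <- 0
  out
}

#' Jerman enhancement function
#'
#' The ratio-based vesselness response: 0 where the cross-sectional
#' eigenvalue or the regularized eigenvalue is non-positive; a plateau of 1
#' where `lam2 >= lam_rho / 2 > 0`; otherwise
#' `lam2^2 * (lam_rho - lam2) * (3 / (lam2 + lam_rho))^3`. Always in
#' \[0, 1\]. Vectorized over matrices or vectors of equal shape.
#'
#' @param lam2 Larger-magnitude Hessian eigenvalue(s), sign-adjusted so
#'   vessels give positive values.
#' @param lam_rho Regularized eigenvalue(s) from [regularize_lambda()].
#' @return Response value(s) in \[0, 1\], same shape as the input.
#' @export
jerman_response <- function(lam2, lam_rho) {
  out <- lam2^2 * (lam_rho - lam2) * (3 / (lam2 + lam_rho))^3
  out[lam2 >= lam_rho / 2 & lam_rho > 0] <- 1
  out[lam2 <= 0 | lam_rho <= 0] <- 0
  if (is.matrix(lam2)) dim(out) <- dim(lam2)
  out
}

#' Multiscale Jerman vesselness
#'
#' For each scale sigma in `seq(s_min, s_max, s_step)`: compute the
#' scale-normalized Hessian, its eigenvalues (negated for bright-on-dark
#' polarity), regularize the larger eigenvalue per scale, evaluate the
#' enhancement function pointwise; the final response is the pointwise
#' maximum over scales.
#'
#' @param img 2D numeric matrix with values in \[0, 1\].
#' @param params A [jerman_params()] object.
#' @param keep_scales If `TRUE`, attach the per-scale response maps.
#' @return A list of class `vesselness_map` with the `response` matrix in
#'   \[0, 1\], `params`, and optionally `per_scale` (named list by sigma).
#' @examples
#' ph <- make_tube(64, 64, radius = 3, angle = 0)
#' v <- vesselness(ph$image, jerman_params(s_min = 2, s_max = 4, s_step = 1))
#' range(v$response)
#' @export
vesselness <- function(img, params = jerman_params(), keep_scales = FALSE) {
  stopifnot(is.matrix(img), all(is.finite(img)))
  scales <- seq(params$s_min, params$s_max, by = params$s_step)
  response <- matrix(0, nrow(img), ncol(img))
  per_scale <- if (keep_scales) vector("list", length(scales)) else NULL
  for (i in seq_along(scales)) {
    h <- hessian_at_scale(img, scales[i])
    ev <- eigenvalues_2x2(h)
    lam2 <- ev$lam2
    if (params$polarity == "bright-on-dark") lam2 <- -lam2
    lam_rho <- regularize_lambda(lam2, params$tau)
    vs <- jerman_response(lam2, lam_rho)
    response <- pmax(response, vs)
    if (keep_scales) per_scale[[i]] <- vs
  }
  if (keep_scales) names(per_scale) <- format(scales)
  structure(list(response = response, params = params, per_scale = per_scale),
            class = "vesselness_map")
}
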