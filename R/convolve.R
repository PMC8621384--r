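#' @keywords internal
#' Reflect-padded 1D correlation along matrix rows/columns, as a dense
#' operator matrix. For an n-vector and a kernel k of radius r (length 2r+1),
#' the result at i is sum_t k[t] * x[reflect(i + t)], t = -r..r, with
#' half-sample-free reflection (abcb|abcd|cba style: index reflection about
#' the edge pixels).
conv1d_operator <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  stopifnot(length(kernel) %% 2L == 1L)
  if (2L * r + 1L > 2L * n - 1L) {
    stop("vesselx: kernel radius ", r, " too large for extent ", n,
         " (degenerate input)", call. = FALSE)
  }
  op <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- i + seq(-r, r)
    # reflect about edge pixels: 0 -> 2, -1 -> 3, n+1 -> n-1, ...
    idx <- ifelse(idx < 1L, 2L - idx, idx)
    idx <- ifelse(idx > n, 2L * n - idx, idx)
    for (t in seq_along(idx)) {
      op[i, idx[t]] <- op[i, idx[t]] + kernel[t]
    }
  }
  op
}

#' @keywords internal
#' Reflect-pad the rows of a matrix by r on each side (same reflection
#' convention as conv1d_operator: about the edge pixels).
reflect_pad_rows <- function(img, r) {
  n <- nrow(img)
  idx <- c((r + 1L):2L, seq_len(n), (n - 1L):(n - r))
  img[idx, , drop = FALSE]
}

# FFT correlation of each column with a centered kernel, reflect padding.
conv1d_fft_rows <- function(img, kernel) {
  r <- (length(kernel) - 1L) / 2L
  n <- nrow(img)
  padded <- reflect_pad_rows(img, r)
  m <- stats::nextn(nrow(padded) + 2L * r, c(2, 3, 5))
  kf <- stats::fft(c(rev(kernel), rep(0, m - length(kernel))))
  xf <- stats::mvfft(rbind(padded, matrix(0, m - nrow(padded), ncol(img))))
  out <- Re(stats::mvfft(xf * kf, inverse = TRUE)) / m
  out[(2L * r + 1L):(2L * r + n), , drop = FALSE]
}

#' @keywords internal
#' Separable correlation with reflect padding: kernel_row applied along rows
#' (i.e. down columns, the y direction), kernel_col along columns (x).
#' Small problems use dense operator matrices; larger ones FFT.
conv_separable <- function(img, kernel_row, kernel_col) {
  use_fft <- nrow(img) * ncol(img) > 128^2 ||
    max(length(kernel_row), length(kernel_col)) > 65L
  if (use_fft) {
    t(conv1d_fft_rows(t(conv1d_fft_rows(img, kernel_row)), kernel_col))
  } else {
    opr <- conv1d_operator(nrow(img), kernel_row)
    opc <- conv1d_operator(ncol(img), kernel_col)
    opr %*% img %*% t(opc)
  }
}

#' @keywords internal
#' Discrete Gaussian kernel and its first/second derivative kernels at
#' standard deviation sigma, calibrated so that polynomial inputs up to
#' degree two are differentiated exactly:
#'   smoothing: sum k0 = 1;  first: sum k1 = 0, sum t*k1 = 1 (correlation
#'   convention, so k1 ~ -g'); second: sum k2 = 0, sum t^2*k2 = 2.
gaussian_kernels <- function(sigma, truncate = 4) {
  r <- max(1L, as.integer(ceiling(truncate * sigma)))
  t <- seq(-r, r)
  g <- exp(-t^2 / (2 * sigma^2))
  k0 <- g / sum(g)
  k1 <- t * g                       # proportional to -g'(t)
  k1 <- k1 - mean(k1)               # enforce zero DC (already 0 by symmetry)
  k1 <- k1 / sum(t * k1)
  k2 <- (t^2 / sigma^2 - 1) * g     # proportional to g''(t)
  k2 <- k2 - mean(k2)               # exact zero response to constants
  k2 <- k2 * (2 / sum(t^2 * k2))
  list(smooth = k0, d1 = k1, d2 = k2, radius = r)
}
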