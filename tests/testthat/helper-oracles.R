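# Independent reference implementations used as oracles. These are written
# as plain per-pixel loops with their own kernel construction and reflect
# indexing, deliberately sharing no code with the package internals.

reflect_index <- function(i, n) {
  if (i < 1L) return(2L - i)
  if (i > n) return(2L * n - i)
  i
}

# Sampled Gaussian kernels, calibrated exactly like a textbook discrete
# differentiator: zero DC for derivative kernels, unit response to t and
# t^2/2 for first/second derivatives, unit sum for smoothing.
oracle_kernels <- function(sigma) {
  r <- max(1, ceiling(4 * sigma))
  t <- -r:r
  g <- exp(-t^2 / (2 * sigma^2))
  k0 <- g / sum(g)
  k1 <- t * g
  k1 <- k1 / sum(t * k1)
  k2 <- (t^2 / sigma^2 - 1) * g
  k2 <- k2 - mean(k2)
  k2 <- k2 * 2 / sum(t^2 * k2)
  list(k0 = k0, k1 = k1, k2 = k2, r = r)
}

# Direct (quadruple-loop) correlation of separable kernels with reflect
# padding; kr along rows, kc along columns.
oracle_conv <- function(img, kr, kc) {
  n1 <- nrow(img); n2 <- ncol(img)
  rr <- (length(kr) - 1L) / 2L
  rc <- (length(kc) - 1L) / 2L
  tmp <- matrix(0, n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    acc <- 0
    for (t in -rr:rr) {
      acc <- acc + kr[t + rr + 1L] * img[reflect_index(i + t, n1), j]
    }
    tmp[i, j] <- acc
  }
  out <- matrix(0, n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    acc <- 0
    for (t in -rc:rc) {
      acc <- acc + kc[t + rc + 1L] * tmp[i, reflect_index(j + t, n2)]
    }
    out[i, j] <- acc
  }
  out
}

# Unvectorized multiscale vesselness for dark structures: per-pixel 2x2
# eigen via base::eigen, scalar regularization and response.
oracle_vesselness <- function(img, tau, scales) {
  n1 <- nrow(img); n2 <- ncol(img)
  best <- matrix(0, n1, n2)
  for (s in scales) {
    k <- oracle_kernels(s)
    hxx <- s^2 * oracle_conv(img, k$k0, k$k2)
    hxy <- s^2 * oracle_conv(img, k$k1, k$k1)
    hyy <- s^2 * oracle_conv(img, k$k2, k$k0)
    lam2 <- matrix(0, n1, n2)
    for (i in seq_len(n1)) for (j in seq_len(n2)) {
      e <- eigen(matrix(c(hxx[i, j], hxy[i, j], hxy[i, j], hyy[i, j]), 2, 2),
                 symmetric = TRUE, only.values = TRUE)$values
      e <- e[order(abs(e), e)]
      lam2[i, j] <- e[2]
    }
    m <- max(lam2)
    for (i in seq_len(n1)) for (j in seq_len(n2)) {
      l2 <- lam2[i, j]
      lr <- if (m <= 0) 0
            else if (l2 > tau * m) l2
            else if (l2 > 0) tau * m
            else 0
      v <- if (l2 <= 0 || lr <= 0) 0
           else if (l2 >= lr / 2) 1
           else l2^2 * (lr - l2) * (3 / (l2 + lr))^3
      if (v > best[i, j]) best[i, j] <- v
    }
  }
  best
}

# Per-pixel mean-C thresholding with reflect padding.
oracle_mean_c <- function(img, w, cc) {
  n1 <- nrow(img); n2 <- ncol(img)
  r <- (w - 1L) / 2L
  out <- matrix(0L, n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    acc <- 0
    for (a in -r:r) for (b in -r:r) {
      acc <- acc + img[reflect_index(i + a, n1), reflect_index(j + b, n2)]
    }
    if (img[i, j] - acc / w^2 > cc) out[i, j] <- 1L
  }
  out
}

# Small, quick phantom spec for unit tests.
small_tree_spec <- function(seed = 1, ...) {
  phantom_spec(height = 128, width = 128, n_branches = 6,
               radius_range = c(2, 4), seed = seed, ...)
}

# Fast pipeline config for unit tests (few scales, small window).
fast_config <- function(...) {
  pipeline_config(jerman = jerman_params(s_min = 2, s_max = 6, s_step = 1),
                  threshold = threshold_params(window = 7), ...)
}
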