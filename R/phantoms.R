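#' Specification for synthetic vessel phantoms
#'
#' Phantoms emulate the conditions of fundus photography that make vessel
#' extraction hard: dark curvilinear vessels of varying radius on a
#' brighter, unevenly illuminated circular field of view, with additive
#' noise, plus an exact ground-truth mask.
#'
#' @param height,width Image size in pixels. Default 584 x 565 (the frame
#'   geometry of a standard fundus test image).
#' @param n_branches Target number of vessel segments in the tree.
#'   Default 13.
#' @param radius_range Min/max vessel radius in pixels; must lie within
#'   `[1, min(height, width) / 8]`. Default `c(2.5, 6.5)`, the span from
#'   thin peripheral vessels to the main arcades at this resolution.
#' @param profile Gaussian cross-section depth (vessel contrast) in
#'   \[0, 1\]. Default 0.5.
#' @param background Base field intensity; `background - profile` must be
#'   non-negative. Default 0.8.
#' @param vignette Radial illumination falloff amplitude (fraction of
#'   `background` lost at the field edge). Default 0.15.
#' @param noise_sigma Additive Gaussian noise standard deviation.
#'   Default 0.01.
#' @param seed Integer RNG seed; identical specs generate bit-identical
#'   phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 584, width = 565, n_branches = 13,
                         radius_range = c(2.5, 6.5), profile = 0.5,
                         background = 0.8, vignette = 0.15,
                         noise_sigma = 0.01, seed = 1L) {
  stopifnot(height >= 32, width >= 32,
            radius_range[1] >= 1, radius_range[2] >= radius_range[1],
            radius_range[2] <= min(height, width) / 8,
            profile >= 0, profile <= 1, background - profile >= 0,
            background <= 1, vignette >= 0, vignette < 1, noise_sigma >= 0)
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_branches = as.integer(n_branches),
                 radius_range = as.numeric(radius_range),
                 profile = profile, background = background,
                 vignette = vignette, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

with_phantom_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

# Stamp a Gaussian ridge sample and its truth disk at (r0, c0); depth and
# mask matrices are modified in the caller via returned patches.
stamp_point <- function(depth, truth, r0, c0, radius, profile) {
  sig <- radius / sqrt(2 * log(2))   # half-maximum depth at the mask edge
  half <- ceiling(max(3 * sig, radius + 1))
  rr <- max(1L, floor(r0 - half)):min(nrow(depth), ceiling(r0 + half))
  cc <- max(1L, floor(c0 - half)):min(ncol(depth), ceiling(c0 + half))
  if (length(rr) == 0L || length(cc) == 0L) return(list(depth = depth,
                                                        truth = truth))
  d2 <- outer((rr - r0)^2, (cc - c0)^2, `+`)
  depth[rr, cc] <- pmax(depth[rr, cc], profile * exp(-d2 / (2 * sig^2)))
  truth[rr, cc] <- pmax(truth[rr, cc], (d2 <= radius^2) * 1L)
  list(depth = depth, truth = truth)
}

#' Straight tube phantom
#'
#' A dark ridge of Gaussian cross-section through the image center at the
#' given angle, on a constant background. The truth mask contains every
#' pixel within `radius` of the centerline. Deterministic given its
#' arguments; noise (if any in `spec`) is seeded.
#'
#' @param height,width Image size in pixels.
#' @param radius Tube radius in pixels (>= 1); the Gaussian cross-section
#'   uses `sigma = radius / 2`.
#' @param angle Centerline angle in degrees (0 = horizontal).
#' @param spec A [phantom_spec()] providing `background`, `profile`,
#'   `noise_sigma` and `seed`.
#' @return List with `image` (matrix in \[0, 1\]) and `truth` (0/1 matrix).
#' @examples
#' ph <- make_tube(64, 64, radius = 4, angle = 45)
#' @export
make_tube <- function(height, width, radius, angle,
                      spec = phantom_spec(height = height, width = width,
                                          noise_sigma = 0)) {
  stopifnot(radius >= 1)
  cy <- floor(height / 2) + 1L
  cx <- floor(width / 2) + 1L
  a <- angle * pi / 180
  sa <- sin(a); ca <- cos(a)
  if (abs(sa) < 1e-12) sa <- 0   # keep axis-aligned boundary ties exact
  if (abs(ca) < 1e-12) ca <- 0
  row <- matrix(seq_len(height), height, width)
  col <- matrix(seq_len(width), height, width, byrow = TRUE)
  # distance to the line through (cy, cx) with direction (ca, sa)
  d <- abs(-sa * (col - cx) + ca * (row - cy))
  sig <- radius / sqrt(2 * log(2))   # half-maximum depth at the mask edge
  img <- spec$background - spec$profile * exp(-d^2 / (2 * sig^2))
  truth <- (d <= radius) * 1L
  dim(truth) <- dim(img)
  if (spec$noise_sigma > 0) {
    img <- with_phantom_seed(spec$seed,
      img + matrix(stats::rnorm(height * width, 0, spec$noise_sigma),
                   height, width))
  }
  list(image = pmin(pmax(img, 0), 1), truth = truth)
}

#' Branching vessel-tree phantom
#'
#' A random binary tree of smooth curved segments (child radius tapering
#' below the parent's) rendered as dark Gaussian ridges inside a circular
#' field of view with radial vignette illumination and additive Gaussian
#' noise. The exterior of the field is near-black, as in real fundus
#' frames. Identical seeds produce bit-identical output.
#'
#' @param spec A [phantom_spec()].
#' @return List with `image`, `truth` (0/1), `fov` (0/1) and `spec`.
#' @examples
#' ph <- make_vessel_tree(phantom_spec(height = 128, width = 128, seed = 7))
#' mean(ph$truth[ph$fov > 0])
#' @export
make_vessel_tree <- function(spec = phantom_spec()) {
  h <- spec$height; w <- spec$width
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  fov_r <- 0.48 * min(h, w)
  row <- matrix(seq_len(h), h, w)
  col <- matrix(seq_len(w), h, w, byrow = TRUE)
  rho2 <- (row - cy)^2 + (col - cx)^2
  fov <- (rho2 <= fov_r^2) * 1L
  dim(fov) <- c(h, w)

  with_phantom_seed(spec$seed, {
    depth <- matrix(0, h, w)
    truth <- matrix(0L, h, w)
    rmin <- spec$radius_range[1]; rmax <- spec$radius_range[2]
    # queue of segments: start point, heading, radius, remaining depth
    start_angle <- stats::runif(1, 0, 2 * pi)
    queue <- list(list(
      r = cy + 0.9 * fov_r * sin(start_angle),
      c = cx + 0.9 * fov_r * cos(start_angle),
      heading = start_angle + pi + stats::runif(1, -0.3, 0.3),
      radius = rmax))
    segs <- 0L
    while (length(queue) > 0L && segs < spec$n_branches) {
      seg <- queue[[1L]]; queue <- queue[-1L]
      segs <- segs + 1L
      len <- stats::runif(1, 0.35, 0.6) * fov_r
      curv <- stats::runif(1, -0.012, 0.012)      # radians per pixel step
      p <- seg
      steps <- max(2L, ceiling(len))
      for (i in seq_len(steps)) {
        p$heading <- p$heading + curv
        p$r <- p$r + sin(p$heading)
        p$c <- p$c + cos(p$heading)
        if ((p$r - cy)^2 + (p$c - cx)^2 > (0.95 * fov_r)^2) break
        st <- stamp_point(depth, truth, p$r, p$c, seg$radius, spec$profile)
        depth <- st$depth; truth <- st$truth
      }
      if (seg$radius * 0.75 >= rmin) {
        split <- stats::runif(1, 0.35, 0.6)
        for (sgn in c(-1, 1)) {
          queue[[length(queue) + 1L]] <- list(
            r = p$r, c = p$c,
            heading = p$heading + sgn * stats::runif(1, 0.3, 0.7),
            radius = max(rmin, seg$radius * stats::runif(1, 0.65, 0.85)))
        }
      }
    }
    vign <- 1 - spec$vignette * rho2 / fov_r^2
    img <- spec$background * vign - depth
    img[fov == 0] <- 0.02
    if (spec$noise_sigma > 0) {
      img <- img + matrix(stats::rnorm(h * w, 0, spec$noise_sigma), h, w)
    }
    truth[fov == 0L] <- 0L
    list(image = pmin(pmax(img, 0), 1), truth = truth, fov = fov,
         spec = spec)
  })
}
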