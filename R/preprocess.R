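#' Load a fundus image or mask raster
#'
#' Reads PNG, TIFF, JPEG (via EBImage) and PPM/PGM rasters into a
#' floating-point intensity array scaled to \[0, 1\] by the integer type
#' maximum. Single-channel files yield a 2D matrix with origin at the top
#' left and `pixels[row, col]` indexing; color files a height x width x 3
#' array.
#'
#' @param path Path to the raster file.
#' @return An object of class `fundus_image`: a list with `pixels` (matrix
#'   or 3-channel array in \[0, 1\]) and `fov` (`NULL` unless attached
#'   later).
#' @export
load_image <- function(path) {
  if (!file.exists(path)) {
    stop("vesselx: cannot read image: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "gif") {
    stop("vesselx: GIF input is not supported (", path,
         "); convert masks to PNG first", call. = FALSE)
  }
  px <- if (ext %in% c("ppm", "pgm")) {
    read_pnm(path)
  } else {
    img <- tryCatch(EBImage::readImage(path),
                    error = function(e) stop("vesselx: unreadable image ",
                                             path, ": ", conditionMessage(e),
                                             call. = FALSE))
    a <- EBImage::imageData(img)       # EBImage stores (x, y[, channel])
    if (length(dim(a)) == 2L) {
      t(a)
    } else {
      nch <- dim(a)[3L]
      if (nch == 1L) t(a[, , 1L])
      else aperm(a[, , 1:3, drop = FALSE], c(2L, 1L, 3L))  # drop alpha
    }
  }
  if (!all(is.finite(px)) || min(px) < 0 || max(px) > 1 + 1e-9) {
    stop("vesselx: intensities outside [0,1] after load: ", path,
         call. = FALSE)
  }
  structure(list(pixels = pmin(px, 1), fov = NULL), class = "fundus_image")
}

# Minimal PPM/PGM (P2/P3/P5/P6) reader; values rescaled by the stated maxval.
read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L)
  if (!magic %in% c("P2", "P3", "P5", "P6")) {
    stop("vesselx: unsupported PNM flavor in ", path, call. = FALSE)
  }
  tokens <- integer(0)
  next_token <- function() {
    repeat {
      ch <- readChar(con, 1L)
      if (length(ch) == 0L || ch == "") stop("vesselx: truncated PNM header",
                                             call. = FALSE)
      if (ch == "#") { repeat { c2 <- readChar(con, 1L)
                                if (c2 == "\n" || c2 == "") break } ; next }
      if (grepl("[0-9]", ch)) {
        tok <- ch
        repeat {
          c2 <- readChar(con, 1L)
          if (!grepl("[0-9]", c2)) break
          tok <- paste0(tok, c2)
        }
        return(as.integer(tok))
      }
    }
  }
  w <- next_token(); h <- next_token(); maxval <- next_token()
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- w * h * nch
  vals <- if (magic %in% c("P5", "P6")) {
    if (maxval < 256) as.numeric(readBin(con, "integer", n, size = 1L,
                                         signed = FALSE))
    else as.numeric(readBin(con, "integer", n, size = 2L, signed = FALSE,
                            endian = "big"))
  } else {
    scan(con, what = numeric(), n = n, quiet = TRUE)
  }
  if (length(vals) < n) stop("vesselx: truncated PNM data in ", path,
                             call. = FALSE)
  if (nch == 1L) {
    matrix(vals / maxval, nrow = h, ncol = w, byrow = TRUE)
  } else {
    a <- array(0, c(h, w, 3L))
    for (k in 1:3) a[, , k] <- matrix(vals[seq(k, n, by = 3L)] / maxval,
                                      nrow = h, ncol = w, byrow = TRUE)
    a
  }
}

#' Load a binary mask raster
#'
#' Loads a raster with [load_image()] and binarizes it at intensity > 0
#' (the convention of manually annotated vessel masks, which are stored as
#' 0/255 images).
#'
#' @param path Path to the mask raster.
#' @return 0/1 integer matrix.
#' @export
load_mask <- function(path) {
  px <- load_image(path)$pixels
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  (px > 0) * 1L
}

#' Write a binary mask as an 8-bit PNG
#'
#' @param mask 0/1 matrix.
#' @param path Output path (PNG).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  EBImage::writeImage(t(mask * 1), path, type = "png")
  invisible(path)
}

#' Extract the working (green) channel
#'
#' Vessels show the strongest contrast in the green channel of fundus
#' photographs, so all downstream filtering operates on it. 2D input passes
#' through unchanged; an attached field-of-view mask is carried over.
#'
#' @param img A `fundus_image` or a numeric matrix / 3-channel array.
#' @return A 2D `fundus_image`.
#' @export
extract_green <- function(img) {
  fov <- NULL
  if (inherits(img, "fundus_image")) { fov <- img$fov; img <- img$pixels }
  px <- if (is.matrix(img)) {
    img
  } else if (length(dim(img)) == 3L && dim(img)[3L] == 3L) {
    img[, , 2L]
  } else {
    stop("vesselx: expected a 2D image or a 3-channel array", call. = FALSE)
  }
  structure(list(pixels = px, fov = fov), class = "fundus_image")
}

#' Estimate the field-of-view mask of a fundus image
#'
#' The camera aperture is near-black outside the circular field of view.
#' Pixels above `luminance_threshold` are kept, the largest 8-connected
#' component is retained and its holes filled.
#'
#' @param img 2D numeric matrix or 2D `fundus_image`.
#' @param luminance_threshold Fraction of full scale in (0, 1). Default 0.1.
#' @return 0/1 integer matrix.
#' @export
compute_fov_mask <- function(img, luminance_threshold = 0.1) {
  if (inherits(img, "fundus_image")) img <- img$pixels
  stopifnot(is.matrix(img), luminance_threshold > 0, luminance_threshold < 1)
  raw <- img > luminance_threshold
  if (!any(raw)) {
    stop("vesselx: empty field-of-view mask (no pixel above threshold)",
         call. = FALSE)
  }
  lab <- label_components(raw * 1L)
  sizes <- tabulate(lab[lab > 0L])
  keep <- (lab == which.max(sizes))
  filled <- EBImage::fillHull(keep * 1)
  matrix(as.integer(filled > 0), nrow(img), ncol(img))
}

#' Suppress the aperture rim of a fundus image
#'
#' The bright rim of the camera aperture produces strong spurious Hessian
#' responses. The field of view is eroded by `erosion_radius` and every
#' pixel outside the eroded mask is replaced by the mean intensity of the
#' eroded-away rim band (a flat fill matched to the boundary intensity, so
#' second derivatives at the former rim vanish even under vignette
#' illumination; when the band is empty the mean over the whole field is
#' used). Pixels strictly inside the eroded mask are never altered.
#'
#' @param img 2D numeric matrix or 2D `fundus_image`.
#' @param fov 0/1 field-of-view matrix.
#' @param erosion_radius Non-negative integer radius in pixels. Default 5.
#' @return 2D numeric matrix in \[0, 1\].
#' @export
suppress_border <- function(img, fov, erosion_radius = 5) {
  if (inherits(img, "fundus_image")) img <- img$pixels
  stopifnot(is.matrix(img), all(dim(fov) == dim(img)), erosion_radius >= 0)
  eroded <- if (erosion_radius == 0) {
    fov > 0
  } else {
    EBImage::erode(fov * 1,
                   EBImage::makeBrush(2L * as.integer(erosion_radius) + 1L,
                                      "disc")) > 0
  }
  if (!any(eroded)) {
    stop("vesselx: erosion removed the entire field of view",
         call. = FALSE)
  }
  band <- fov > 0 & !eroded
  fill <- if (any(band)) mean(img[band]) else mean(img[fov > 0])
  out <- img
  out[!eroded] <- fill
  out
}

#' 8-connected component labeling
#'
#' Two-pass union-find labeling of a binary matrix under 8-connectivity.
#'
#' @param mask 0/1 matrix.
#' @return Integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask) {
  n1 <- nrow(mask); n2 <- ncol(mask)
  lab <- matrix(0L, n1, n2)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]
                                                 i <- parent[i] }; i }
  nxt <- 0L
  for (c in seq_len(n2)) for (r in seq_len(n1)) {
    if (mask[r, c] == 0) next
    nb <- integer(0)
    if (r > 1L && lab[r - 1L, c] > 0L) nb <- c(nb, lab[r - 1L, c])
    if (c > 1L) {
      if (lab[r, c - 1L] > 0L) nb <- c(nb, lab[r, c - 1L])
      if (lab[r - 1L, c - 1L] > 0L && r > 1L) nb <- c(nb, lab[r - 1L, c - 1L])
      if (r < n1 && lab[r + 1L, c - 1L] > 0L) nb <- c(nb, lab[r + 1L, c - 1L])
    }
    if (length(nb) == 0L) {
      nxt <- nxt + 1L
      parent[nxt] <- nxt
      lab[r, c] <- nxt
    } else {
      roots <- vapply(unique(nb), find, integer(1))
      keep <- min(roots)
      for (rt in roots) parent[rt] <- keep
      lab[r, c] <- keep
    }
  }
  if (nxt == 0L) return(lab)
  roots <- vapply(seq_len(nxt), find, integer(1))
  relabel <- match(roots, sort(unique(roots)))
  pos <- which(lab > 0L)
  lab[pos] <- relabel[lab[pos]]
  lab
}
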