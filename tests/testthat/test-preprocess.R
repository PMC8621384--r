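test_that("masks survive a write/reload round trip bit-exactly", {
  set.seed(40)
  mask <- matrix(as.integer(runif(32 * 24) > 0.5), 24, 32)
  path <- tempfile(fileext = ".png")
  write_mask(mask, path)
  expect_identical(load_mask(path), mask)
  unlink(path)
})

test_that("intensities rescale by the integer type maximum on load", {
  # 8-bit PGM with the extreme values and a 16-bit PGM midpoint
  p8 <- tempfile(fileext = ".pgm")
  writeLines(c("P2", "2 1", "255", "0 255"), p8)
  img <- load_image(p8)
  expect_equal(as.numeric(img$pixels), c(0, 1))

  p16 <- tempfile(fileext = ".pgm")
  con <- file(p16, "wb")
  writeChar("P5\n2 1\n65535\n", con, eos = NULL)
  writeBin(c(0L, 32768L), con, size = 2, endian = "big")
  close(con)
  img16 <- load_image(p16)
  expect_equal(as.numeric(img16$pixels), c(0, 32768 / 65535))
  unlink(c(p8, p16))
})

test_that("unreadable or unsupported inputs raise input-format errors", {
  expect_error(load_image(tempfile()), "cannot read")
  gif <- tempfile(fileext = ".gif")
  writeLines("GIF89a", gif)
  expect_error(load_image(gif), "GIF")
  unlink(gif)
})

test_that("green-channel extraction selects channel 2 and is idempotent", {
  arr <- array(0, c(4, 5, 3))
  arr[, , 1] <- 10 / 255; arr[, , 2] <- 200 / 255; arr[, , 3] <- 30 / 255
  g <- extract_green(arr)
  expect_true(is.matrix(g$pixels))
  expect_equal(g$pixels, matrix(200 / 255, 4, 5))
  expect_equal(extract_green(g)$pixels, g$pixels)

  m <- matrix(runif(12), 3, 4)
  expect_equal(extract_green(m)$pixels, m)
  expect_error(extract_green(array(0, c(3, 3, 2))), "3-channel")
})

test_that("fov estimation keeps the filled largest component", {
  n <- 256
  rr <- matrix(seq_len(n), n, n); cc <- t(rr)
  disk <- ((rr - 128)^2 + (cc - 128)^2 <= 100^2)
  img <- ifelse(disk, 0.5, 0)
  # a hole inside and a small spurious bright blob outside
  img[120:124, 120:124] <- 0
  img[10:12, 10:12] <- 0.9
  fov <- compute_fov_mask(img, 0.1)
  expect_lt(abs(sum(fov) - pi * 100^2) / (pi * 100^2), 0.01)
  expect_true(all(fov[120:124, 120:124] == 1))  # hole filled
  expect_true(all(fov[10:12, 10:12] == 0))      # blob dropped

  expect_error(compute_fov_mask(matrix(0, 8, 8)), "empty")
})

test_that("border suppression only alters the rim and kills rim responses", {
  img <- matrix(0.4, 32, 32)
  fov <- matrix(1L, 32, 32)
  expect_equal(suppress_border(img, fov, 0), img)
  expect_equal(suppress_border(img, fov, 3), img)

  set.seed(41)
  img <- matrix(runif(64 * 64), 64, 64)
  rr <- matrix(seq_len(64), 64, 64); cc <- t(rr)
  fov <- ((rr - 32)^2 + (cc - 32)^2 <= 28^2) * 1L
  out <- suppress_border(img, fov, 4)
  eroded <- EBImage::erode(fov * 1, EBImage::makeBrush(9, "disc")) > 0
  expect_identical(out[eroded], img[eroded])

  expect_error(suppress_border(img, fov, 40), "entire field")
})

test_that("rim suppression removes the aperture step response", {
  n <- 128
  rr <- matrix(seq_len(n), n, n); cc <- t(rr)
  fov <- ((rr - 64)^2 + (cc - 64)^2 <= 55^2) * 1L
  img <- ifelse(fov > 0, 0.5, 0)   # hard step exactly at the fov boundary
  p <- jerman_params(s_min = 2, s_max = 4, s_step = 1)
  rim <- fov > 0 &
    (EBImage::erode(fov * 1, EBImage::makeBrush(11, "disc")) == 0)
  raw_resp <- vesselness(img, p)$response
  sup_resp <- vesselness(suppress_border(img, fov, 5), p)$response
  expect_gt(max(raw_resp[rim]), 1e-3)
  expect_lt(max(sup_resp[rim]), 1e-3)
})

test_that("component labeling is 8-connected", {
  m <- matrix(0L, 6, 6)
  m[cbind(1:5, 1:5)] <- 1L   # diagonal chain
  m[1, 6] <- 1L              # isolated corner
  lab <- label_components(m)
  expect_equal(max(lab), 2L)
  expect_equal(length(unique(lab[cbind(1:5, 1:5)])), 1L)
})
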