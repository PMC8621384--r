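test_that("scale-normalized Hessian reproduces analytic second derivatives", {
  n <- 33
  flat <- matrix(0.37, n, n)
  h <- hessian_at_scale(flat, 2)
  expect_equal(max(abs(h$hxx)), 0, tolerance = 1e-12)
  expect_equal(max(abs(h$hxy)), 0, tolerance = 1e-12)
  expect_equal(max(abs(h$hyy)), 0, tolerance = 1e-12)

  # f = x^2 (x = column): d2f/dx2 = 2, so hxx = 2 sigma^2 in the interior
  fx2 <- outer(rep(1, n), as.numeric(seq_len(n))^2)
  for (sg in c(1.5, 2, 3)) {
    h <- hessian_at_scale(fx2, sg)
    expect_lt(abs(h$hxx[17, 17] - 2 * sg^2), 1e-6)
    expect_lt(abs(h$hyy[17, 17]), 1e-6)
  }

  # f = x * y: d2f/dxdy = 1, so hxy = sigma^2
  fxy <- outer(as.numeric(seq_len(n)), as.numeric(seq_len(n)))
  h <- hessian_at_scale(fxy, 2)
  expect_lt(abs(h$hxy[17, 17] - 4), 1e-6)

  expect_error(hessian_at_scale(matrix(0, 8, 8), 50), "degenerate")
})

test_that("closed-form 2x2 eigenvalues match a generic eigensolver", {
  h <- list(hxx = matrix(2, 1, 1), hxy = matrix(0, 1, 1),
            hyy = matrix(1, 1, 1))
  ev <- eigenvalues_2x2(h)
  expect_equal(c(ev$lam1, ev$lam2), c(1, 2))

  # equal-magnitude tie ordered ascending by signed value
  h <- list(hxx = matrix(0, 1, 1), hxy = matrix(1, 1, 1),
            hyy = matrix(0, 1, 1))
  ev <- eigenvalues_2x2(h)
  expect_equal(c(ev$lam1, ev$lam2), c(-1, 1))

  set.seed(42)
  for (i in 1:50) {
    a <- rnorm(1); b <- rnorm(1); c <- rnorm(1)
    ev <- eigenvalues_2x2(list(hxx = matrix(a, 1, 1),
                               hxy = matrix(b, 1, 1),
                               hyy = matrix(c, 1, 1)))
    ref <- eigen(matrix(c(a, b, b, c), 2, 2), symmetric = TRUE)$values
    ref <- ref[order(abs(ref), ref)]
    expect_lt(abs(ev$lam1 - ref[1]), 1e-12)
    expect_lt(abs(ev$lam2 - ref[2]), 1e-12)
    # trace / determinant consistency
    expect_lt(abs(ev$lam1 + ev$lam2 - (a + c)),
              1e-9 * max(1, abs(a + c)))
    expect_lt(abs(ev$lam1 * ev$lam2 - (a * c - b^2)),
              1e-9 * max(1, abs(a * c - b^2)))
  }
})

test_that("eigenvalue cut-off regularization follows its three branches", {
  grid <- matrix(c(10, 7, 3, -2), 2, 2)
  out <- regularize_lambda(grid, 0.5)
  expect_equal(out[grid == 10], 10)  # above the cut: unchanged
  expect_equal(out[grid == 7], 7)
  expect_equal(out[grid == 3], 5)    # positive but below: raised to tau*max
  expect_equal(out[grid == -2], 0)   # non-positive: zero
  expect_equal(regularize_lambda(matrix(-1, 3, 3), 0.5), matrix(0, 3, 3))
})

test_that("enhancement function hits its plateau, zero and cubic branches", {
  expect_equal(jerman_response(-1, 4), 0)
  expect_equal(jerman_response(1, -1), 0)
  expect_equal(jerman_response(2, 4), 1)   # lam2 >= lam_rho/2 > 0
  expect_equal(jerman_response(1, 4), 81 / 125)
  # the cubic branch meets the plateau continuously at lam2 = lam_rho/2
  lr <- 3
  l2 <- lr / 2
  expect_equal(l2^2 * (lr - l2) * (3 / (l2 + lr))^3, 1)
  # bounded in [0, 1] for random inputs
  set.seed(7)
  l2 <- runif(500, -2, 5); lr <- runif(500, -1, 5)
  v <- jerman_response(l2, lr)
  expect_true(all(v >= 0 & v <= 1))
})

test_that("multiscale vesselness matches an unvectorized per-pixel oracle", {
  set.seed(11)
  for (rep in 1:3) {
    img <- matrix(runif(16 * 16), 16, 16)
    scales <- c(1, 1.5, 2)
    v <- vesselness(img, jerman_params(tau = 0.5, s_min = 1, s_max = 2,
                                       s_step = 0.5))
    ref <- oracle_vesselness(img, 0.5, seq(1, 2, 0.5))
    expect_lt(max(abs(v$response - ref)), 1e-9)
  }
})

test_that("vesselness is zero on constants and reduces to one scale", {
  flat <- matrix(0.6, 32, 32)
  v <- vesselness(flat, jerman_params(s_min = 2, s_max = 4, s_step = 1))
  expect_equal(max(v$response), 0)

  set.seed(3)
  img <- matrix(runif(32 * 32), 32, 32)
  v1 <- vesselness(img, jerman_params(s_min = 3, s_max = 3, s_step = 0.5),
                   keep_scales = TRUE)
  expect_equal(v1$response, v1$per_scale[[1]])
})

test_that("enlarging the scale set never decreases the response", {
  set.seed(5)
  img <- matrix(runif(32 * 32), 32, 32)
  v_small <- vesselness(img, jerman_params(s_min = 2, s_max = 3, s_step = 1))
  v_big <- vesselness(img, jerman_params(s_min = 2, s_max = 5, s_step = 1))
  expect_true(all(v_big$response - v_small$response >= -1e-12))
})

test_that("polarity switch mirrors the response on an inverted image", {
  ph <- make_tube(64, 64, radius = 3, angle = 20)
  p_dark <- jerman_params(s_min = 2, s_max = 4, s_step = 1)
  p_bright <- jerman_params(s_min = 2, s_max = 4, s_step = 1,
                            polarity = "bright-on-dark")
  v1 <- vesselness(ph$image, p_dark)
  v2 <- vesselness(1 - ph$image, p_bright)
  expect_equal(v1$response, v2$response, tolerance = 1e-12)
})

test_that("plateau response is invariant under positive contrast scaling", {
  ph <- make_tube(64, 64, radius = 3, angle = 0)
  p <- jerman_params(s_min = 2, s_max = 4, s_step = 1)
  v1 <- vesselness(ph$image, p)$response
  v2 <- vesselness(0.5 * ph$image + 0.25, p)$response
  plateau <- v1 >= 1 - 1e-12
  expect_true(any(plateau))
  expect_true(all(v2[plateau] >= 1 - 1e-12))
})
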