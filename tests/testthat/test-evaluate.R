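test_that("confusion counts enumerate agreement and disagreement", {
  truth <- matrix(0L, 4, 4); truth[cbind(c(1, 2, 3), c(2, 2, 3))] <- 1L
  pred <- matrix(0L, 4, 4); pred[cbind(c(1, 1, 2), c(1, 2, 2))] <- 1L
  cc <- confusion_counts(pred, truth)
  expect_equal(cc$tp, 2); expect_equal(cc$fp, 1)
  expect_equal(cc$fn, 1); expect_equal(cc$tn, 12)

  v <- sum(truth)
  same <- confusion_counts(truth, truth)
  expect_equal(c(same$tp, same$tn, same$fp, same$fn), c(v, 16 - v, 0, 0))
  ones <- confusion_counts(matrix(1L, 4, 4), truth)
  expect_equal(c(ones$tp, ones$fp, ones$tn, ones$fn), c(v, 16 - v, 0, 0))

  expect_error(confusion_counts(matrix(0, 3, 3), truth), "dimensions")
})

test_that("metrics follow the four ratio definitions with NA markers", {
  r <- metrics(list(tp = 8, fp = 2, tn = 88, fn = 2))
  expect_equal(r$sensitivity, 0.8)
  expect_equal(r$specificity, 88 / 90)
  expect_equal(r$accuracy, 0.96)
  expect_equal(r$precision, 0.8)

  perfect <- metrics(list(tp = 5, fp = 0, tn = 10, fn = 0))
  expect_equal(unlist(perfect[, -1]), c(sensitivity = 1, specificity = 1,
                                        accuracy = 1, precision = 1))

  nose <- metrics(list(tp = 0, fp = 0, tn = 10, fn = 0))
  expect_true(is.na(nose$sensitivity))
  expect_true(is.na(nose$precision))
  expect_error(metrics(list(tp = 0, fp = 0, tn = 0, fn = 0)), "all-zero")
})

test_that("aggregation takes unweighted column means and counts skips", {
  rows <- rbind(metrics(list(tp = 8, fp = 2, tn = 88, fn = 2), "a"),
                metrics(list(tp = 4, fp = 4, tn = 90, fn = 2), "b"),
                metrics(list(tp = 0, fp = 0, tn = 99, fn = 1), "c"))
  rep <- aggregate_metrics(rows)
  expect_equal(rep$means$sensitivity,
               mean(c(0.8, 4 / 6, 0)))
  expect_equal(rep$means$precision, mean(c(0.8, 0.5)))  # one NA skipped
  expect_equal(unname(rep$n_undefined["precision"]), 1L)

  single <- aggregate_metrics(metrics(list(tp = 1, fp = 1, tn = 1, fn = 1)))
  expect_equal(single$means$accuracy, single$rows$accuracy)
  expect_error(aggregate_metrics(NULL), "empty")
})

test_that("sensitivity and precision swap under prediction/truth exchange", {
  set.seed(30)
  for (i in 1:5) {
    a <- matrix(as.integer(runif(100) > 0.6), 10, 10)
    b <- matrix(as.integer(runif(100) > 0.4), 10, 10)
    m1 <- metrics(confusion_counts(a, b))
    m2 <- metrics(confusion_counts(b, a))
    expect_equal(m1$sensitivity, m2$precision)
    expect_equal(m1$precision, m2$sensitivity)
  }
})

test_that("accuracy is the prevalence-weighted mix of Se and Sp", {
  set.seed(31)
  for (i in 1:10) {
    cc <- list(tp = sample(1:50, 1), fp = sample(1:50, 1),
               tn = sample(1:50, 1), fn = sample(1:50, 1))
    r <- metrics(cc)
    p <- cc$tp + cc$fn; n <- cc$tn + cc$fp
    expect_equal(r$accuracy,
                 (r$sensitivity * p + r$specificity * n) / (p + n))
  }
})

test_that("restricting the fov can only shrink each count", {
  set.seed(32)
  a <- matrix(as.integer(runif(100) > 0.5), 10, 10)
  b <- matrix(as.integer(runif(100) > 0.5), 10, 10)
  fov <- matrix(0L, 10, 10); fov[3:8, 2:9] <- 1L
  full <- confusion_counts(a, b)
  sub <- confusion_counts(a, b, fov)
  expect_true(all(unlist(sub[c("tp", "fp", "tn", "fn")]) <=
                  unlist(full[c("tp", "fp", "tn", "fn")])))
})

test_that("dice overlap matches its definition", {
  a <- matrix(0L, 4, 4); a[1:2, 1:2] <- 1L
  b <- matrix(0L, 4, 4); b[2:3, 1:2] <- 1L
  expect_equal(dice(a, b), 2 * 2 / (4 + 4))
  expect_equal(dice(a, a), 1)
})

test_that("bundled baseline tables load with their published shape", {
  drive <- curvelet_baseline_metrics("drive")
  chase <- curvelet_baseline_metrics("chase")
  expect_equal(nrow(drive), 20)
  expect_equal(nrow(chase), 14)
  expect_true(all(c("sensitivity", "specificity", "accuracy",
                    "precision") %in% names(drive)))
})
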