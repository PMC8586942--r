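test_that("class weights follow the inverse class-frequency rule", {
  # symmetric mask: both weights 2
  m <- matrix(c(1, 1, 0, 0), 2, 2)
  w <- class_weights(m)
  expect_equal(w$wT, 2)
  expect_equal(w$wF, 2)

  # 512^2 image with 1000 foreground pixels
  P <- 512^2
  w <- class_weights(rep(c(1, 0), c(1000, P - 1000)), P = P)
  expect_equal(w$wT, 262.144)
  expect_equal(w$wF, 262144 / 261144)

  # conservation identity wT * sum(Y) = wF * (P - sum(Y)) = P
  for (sY in c(1, 7, 100, 511)) {
    y <- rep(c(1, 0), c(sY, 1024 - sY))
    w <- class_weights(y)
    expect_equal(w$wT * sY, 1024)
    expect_equal(w$wF * (1024 - sY), 1024)
  }

  expect_error(class_weights(matrix(0, 4, 4)), "degenerate")
  expect_error(class_weights(matrix(1, 4, 4)), "degenerate")
})

test_that("weighted BCE matches hand-computed scalar sums", {
  # 2x2 mask with one foreground pixel, uniform prediction 0.5:
  # wT = 4, wF = 4/3; every pixel's CE is -log(0.5)
  Y <- matrix(c(1, 0, 0, 0), 2, 2)
  Yhat <- matrix(0.5, 2, 2)
  expected <- -log(0.5) * (4 + 3 * (4 / 3))
  expect_equal(weighted_bce(Y, Yhat), expected, tolerance = 1e-12)

  # perfect prediction (up to clamping) -> loss ~ 0
  Yp <- matrix(c(1 - 1e-7, 1e-7, 1e-7, 1e-7), 2, 2)
  expect_lt(weighted_bce(Y, Yp), 1e-5)

  # batch of two identical images equals the single-image loss
  b <- weighted_bce(list(Y, Y), list(Yhat, Yhat))
  expect_equal(b, weighted_bce(Y, Yhat))

  # loss decreases monotonically as predictions move from 0.5 toward Y
  alphas <- seq(0, 0.4, by = 0.1)
  losses <- vapply(alphas, function(a) {
    p <- matrix(0.5, 2, 2) + a * (Y - 0.5) * 2 * 0.9
    weighted_bce(Y, pmin(pmax(p, 0.01), 0.99))
  }, 0)
  expect_true(all(diff(losses) < 0))
})

test_that("confusion counts enumerate pixels correctly", {
  Y <- matrix(0, 8, 8); Y[1:2, 1:2] <- 1           # 4 foreground px
  Yhat <- matrix(0, 8, 8); Yhat[1:4, 1:4] <- 1     # covers all 4 + 12 extra
  cc <- confusion_counts(Y, Yhat)
  expect_equal(cc$TP, 4)
  expect_equal(cc$FP, 12)
  expect_equal(cc$FN, 0)
  expect_equal(cc$TP + cc$FP + cc$FN + cc$TN, 64)

  expect_equal(confusion_counts(Y, Y)$FP, 0)
  expect_equal(confusion_counts(Y, Y)$FN, 0)
  inv <- confusion_counts(Y, 1 - Y)
  expect_equal(inv$TP, 0)
  expect_equal(inv$TN, 0)
})

test_that("metric suite reproduces the recall-weighted worked examples", {
  # recall 1, precision 0.25: F1 = 0.4, rw F1 = 0.4, mIoU = 0.25
  cc <- structure(list(TP = 25, FP = 75, FN = 0, TN = 900),
                  class = "confusion_counts")
  m <- metric_suite(cc)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 0.25)
  expect_equal(m$f1, 0.4)
  expect_equal(m$rw_f1, 0.4)
  expect_equal(m$miou, 0.25)
  expect_equal(m$rw_miou, 0.25)

  # recall 0.4, precision 0.4: F1 = 0.4 but rw F1 only 0.16
  cc <- structure(list(TP = 40, FP = 60, FN = 60, TN = 840),
                  class = "confusion_counts")
  m <- metric_suite(cc)
  expect_equal(m$recall, 0.4)
  expect_equal(m$precision, 0.4)
  expect_equal(m$f1, 0.4)
  expect_equal(m$rw_f1, 0.16)

  # perfect prediction: everything 1
  m <- metric_suite(structure(list(TP = 10, FP = 0, FN = 0, TN = 90),
                              class = "confusion_counts"))
  expect_true(all(unlist(m) == 1))

  # degenerate convention: nothing predicted positive -> precision 0
  m <- metric_suite(structure(list(TP = 0, FP = 0, FN = 5, TN = 95),
                              class = "confusion_counts"))
  expect_equal(m$precision, 0)
  expect_equal(m$f1, 0)
  expect_equal(m$rw_f1, 0)

  expect_error(metric_suite(structure(list(TP = 0, FP = 3, FN = 0, TN = 9),
                                      class = "confusion_counts")),
               "recall undefined")
})

test_that("metric suite agrees with pixel-enumeration oracle on random masks", {
  set.seed(7)
  for (r in 1:20) {
    y <- matrix(rbinom(32 * 32, 1, 0.05), 32, 32)
    if (sum(y) == 0) y[1, 1] <- 1
    p <- matrix(rbinom(32 * 32, 1, 0.08), 32, 32)
    m <- metric_suite(confusion_counts(y, p))
    o <- naive_metrics(y, p)
    expect_equal(unlist(m)[names(o)], o, tolerance = 1e-12)
  }
})

test_that("metric ordering invariants hold over random confusion counts", {
  set.seed(11)
  for (r in 1:200) {
    cc <- structure(list(TP = sample(0:50, 1), FP = sample(0:50, 1),
                         FN = sample(0:50, 1), TN = sample(0:500, 1)),
                    class = "confusion_counts")
    if (cc$TP + cc$FN == 0) next
    m <- metric_suite(cc)
    expect_lte(m$rw_miou, m$miou + 1e-15)
    expect_lte(m$miou, m$f1 + 1e-15)
    expect_lte(m$rw_f1, m$f1 + 1e-15)
    expect_lte(m$f1, max(m$precision, m$recall) + 1e-15)
    expect_gte(m$rw_miou, 0)
  }
})

test_that("pooled counts equal the sum of per-image counts", {
  set.seed(3)
  ys <- lapply(1:4, function(i) matrix(rbinom(64, 1, 0.2), 8, 8))
  ps <- lapply(1:4, function(i) matrix(rbinom(64, 1, 0.2), 8, 8))
  pooled <- pool_counts(Map(confusion_counts, ys, ps))
  allc <- confusion_counts(unlist(ys), unlist(ps))
  expect_equal(unclass(pooled), unclass(allc))
})
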