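# Image-quality, confusion-matrix and statistical metrics.

test_that("MSE/RMSE match hand computations", {
  a <- matrix(c(0, 10), 1, 2); b <- matrix(c(6, 2), 1, 2)
  e <- mse_rmse(a, b)
  expect_equal(e$mse, 50); expect_equal(e$rmse, sqrt(50))
  expect_equal(mse_rmse(a, a), list(mse = 0, rmse = 0))
  expect_equal(mse_rmse(a, a + 1), list(mse = 1, rmse = 1))
  expect_error(mse_rmse(a, matrix(0, 2, 2)), "shape")
})

test_that("PSNR follows its closed form and decreases with error", {
  a <- matrix(0:24, 5, 5)
  expect_equal(psnr(a, a + 1), 20 * log10(255))       # about 48.13 dB
  expect_identical(psnr(a, a), Inf)
  expect_equal(psnr(a, a + 1) - psnr(a, a + 2), 20 * log10(2))
  # strictly decreasing in mse
  offsets <- c(1, 2, 5, 10, 20)
  ps <- vapply(offsets, function(o) psnr(a, a + o), 1)
  expect_true(all(diff(ps) < 0))
})

test_that("UIQI is 1 for identical images and negative under inversion", {
  set.seed(1)
  a <- matrix(runif(64, 0, 255), 8, 8)
  expect_equal(uiqi(a, a), 1)
  sym <- matrix(c(28, 228, 128 + 40, 128 - 40), 4, 4)  # symmetric about 128
  expect_lt(uiqi(sym, 255 - sym), 0)
  # brute-force evaluation on a small pair
  x <- matrix(c(10, 20, 30, 40), 2, 2); y <- matrix(c(12, 18, 33, 41), 2, 2)
  mx <- mean(x); my <- mean(y)
  num <- 4 * stats::cov(c(x), c(y)) * mx * my
  den <- (stats::var(c(x)) + stats::var(c(y))) * (mx^2 + my^2)
  expect_equal(uiqi(x, y), num / den)
  expect_error(uiqi(matrix(5, 2, 2), matrix(5, 2, 2)), "undefined")
})

test_that("confusion counts from masks enumerate all four cells", {
  p <- matrix(c(255, 0, 255, 0), 2, 2)
  t <- matrix(c(255, 0, 0, 0), 2, 2)
  cc <- confusion_from_masks(p, t)
  expect_equal(c(cc$tp, cc$fn, cc$fp, cc$tn), c(1, 0, 1, 2))
  full <- matrix(255, 3, 3)
  cc2 <- confusion_from_masks(full, full)
  expect_equal(c(cc2$tp, cc2$fn, cc2$fp, cc2$tn), c(9, 0, 0, 0))
  cc3 <- confusion_from_masks(full, full * 0)
  expect_equal(cc3$tp + cc3$tn, 0)                    # complement case
  expect_error(confusion_from_masks(full, matrix(0, 2, 2)), "shape")
})

test_that("classification metrics match their definitions", {
  perf <- classification_metrics(confusion_counts(10, 0, 0, 20))
  for (nm in c("sn", "sp", "dice", "jaccard", "accuracy", "auc",
               "precision", "recall", "f1", "mcc"))
    expect_equal(perf[[nm]], 1)
  m <- classification_metrics(confusion_counts(1, 0, 1, 2))
  expect_equal(m$dice, 2 / 3)
  expect_equal(m$jaccard, 1 / 2)
  expect_equal(m$accuracy, 3 / 4)
  expect_equal(m$auc, (1 + 2 / 3) / 2)
  # zero denominators surface as NA, never as silent zero
  z <- classification_metrics(confusion_counts(0, 0, 0, 5))
  expect_true(is.na(z$sn)); expect_true(is.na(z$precision))
  expect_equal(z$sp, 1)
})

test_that("metrics agree with a mask-level recomputation", {
  set.seed(202)
  for (rep in 1:30) {
    p <- (matrix(runif(256), 16, 16) > runif(1, 0.2, 0.8)) * 255
    t <- (matrix(runif(256), 16, 16) > runif(1, 0.2, 0.8)) * 255
    got <- classification_metrics(confusion_from_masks(p, t))
    want <- oracle_metrics_from_masks(p, t)
    for (nm in names(want))
      if (is.finite(want[[nm]])) expect_equal(got[[nm]], want[[nm]])
  }
})

test_that("Dice and Jaccard are linked by the exact identity", {
  set.seed(6)
  for (rep in 1:50) {
    cc <- confusion_counts(sample(0:50, 1), sample(0:50, 1),
                           sample(0:50, 1), sample(1:50, 1))
    m <- classification_metrics(cc)
    if (!is.na(m$jaccard) && !is.na(m$dice))
      expect_equal(m$dice, dice_from_jaccard(m$jaccard))
  }
})

test_that("MCC stays in [-1, 1] and peaks only on perfect agreement", {
  set.seed(17)
  for (rep in 1:50) {
    cc <- confusion_counts(sample(1:30, 1), sample(0:30, 1),
                           sample(0:30, 1), sample(1:30, 1))
    m <- classification_metrics(cc)$mcc
    expect_gte(m, -1); expect_lte(m, 1)
    if (m == 1) expect_true(cc$fn == 0 && cc$fp == 0)
  }
  expect_equal(classification_metrics(confusion_counts(5, 0, 0, 7))$mcc, 1)
})

test_that("printed rates on the published hold-out split reproduce exactly", {
  # hold-out set: 40 melanoma vs 160 non-melanoma; printed sensitivity
  # 100%, specificity 99.38% pin the counts (40, 0, 1, 159)
  cc <- confusion_from_rates(40, 160, 100, 99.38)
  expect_equal(c(cc$tp, cc$fn, cc$fp, cc$tn), c(40, 0, 1, 159))
  p <- classification_metrics(cc)$percent
  expect_equal(p[["accuracy"]], 99.50)
  expect_equal(p[["precision"]], 97.56)
  expect_equal(p[["f1"]], 98.77)
  expect_equal(p[["auc"]], 99.69)
  expect_equal(p[["mcc"]], 98.46)
})

test_that("bounding-box IoU is the true overlap-over-union", {
  a <- bounding_box(0, 0, 10, 10)
  expect_equal(box_iou(a, a), 1)
  expect_equal(box_iou(a, bounding_box(20, 20, 30, 30)), 0)
  b <- bounding_box(0, 5, 10, 15)                     # shifted 5 columns
  expect_equal(box_iou(a, b), 1 / 3)
  expect_error(bounding_box(0, 0, 0, 10), "positive extent")
})

test_that("mean average precision averages defined precisions", {
  perfect <- confusion_counts(5, 0, 0, 5)
  half <- confusion_counts(5, 0, 5, 0)
  expect_equal(mean_average_precision(list(perfect, perfect)), 1,
               ignore_attr = TRUE)
  expect_equal(mean_average_precision(list(perfect, half)), 0.75,
               ignore_attr = TRUE)
  expect_equal(mean_average_precision(list(half)), 0.5, ignore_attr = TRUE)
  und <- confusion_counts(0, 3, 0, 7)
  expect_warning(got <- mean_average_precision(list(perfect, und)))
  expect_equal(got, 1, ignore_attr = TRUE)
  expect_equal(attr(got, "n_undefined"), 1)
  expect_true(is.na(suppressWarnings(mean_average_precision(list(und)))))
})

test_that("image statistics match brute-force moments", {
  con <- matrix(42, 4, 4)
  s <- image_stats(con)
  expect_equal(s$mean, 42)
  expect_true(is.na(s$skewness) && is.na(s$kurtosis))
  # symmetric two-point distribution: skewness 0, kurtosis 1
  two <- matrix(c(0, 255), 4, 4)
  s2 <- image_stats(two)
  expect_equal(s2$skewness, 0)
  expect_equal(s2$kurtosis, 1)
  # explicit four-pixel check
  x <- c(0, 0, 0, 100)
  mu <- mean(x); sig <- sqrt(mean((x - mu)^2))
  s3 <- image_stats(matrix(x, 2, 2))
  expect_equal(s3$mean, 25)
  expect_equal(s3$skewness, mean((x - mu)^3) / sig^3)
  expect_equal(s3$kurtosis, mean((x - mu)^4) / sig^4)
})

test_that("half-up rounding behaves at exactly representable boundaries", {
  expect_equal(round_half_up(0.125), 0.13)      # base round() would give 0.12
  expect_equal(round_half_up(2.5, 0), 3)
  expect_equal(round_half_up(-2.5, 0), -3)
  expect_equal(round_half_up(97.554), 97.55)
  expect_equal(round_half_up(80 / 81 * 100), 98.77)
})
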