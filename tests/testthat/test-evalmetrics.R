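test_that("confusion matrices count true/predicted pairs exactly", {
  y <- rep(0:2, each = 10)
  cm <- confusion_matrix(y, y)
  expect_equal(unclass(cm), diag(10L, 3),  ignore_attr = TRUE)

  cm0 <- confusion_matrix(y, rep(0L, 30))
  expect_equal(unname(cm0[, 1]), c(10L, 10L, 10L))
  expect_true(all(cm0[, 2:3] == 0))

  set.seed(1)
  yt <- sample(0:2, 10, replace = TRUE)
  yp <- sample(0:2, 10, replace = TRUE)
  cm <- confusion_matrix(yt, yp)
  for (i in 0:2) for (j in 0:2) {
    expect_equal(cm[i + 1, j + 1], sum(yt == i & yp == j))
  }
  expect_error(confusion_matrix(0:1, 0:2), "length mismatch")
  expect_error(confusion_matrix(c(0, 5), c(0, 1)), "labels")
})

test_that("the binary metric formulas reproduce hand arithmetic", {
  # TP=50 FP=10 FN=5 TN=35 as a 2-class matrix embedded one-vs-rest
  cm <- matrix(c(35L, 10L, 5L, 50L), 2, 2, byrow = TRUE)
  m <- metrics_report(cm, mode = "binary", positive = 1L)
  expect_equal(m$precision, 50 / 60, tolerance = 1e-12)
  expect_equal(m$sensitivity, 50 / 55, tolerance = 1e-12)
  expect_equal(m$specificity, 35 / 45, tolerance = 1e-12)
  expect_equal(m$accuracy, 0.85, tolerance = 1e-12)
  expect_equal(m$fpr, 1 - m$specificity, tolerance = 1e-15)
  expect_equal(m$fnr, 1 - m$sensitivity, tolerance = 1e-15)
})

test_that("a perfect classifier scores 1 on every rate metric and 0 on errors", {
  cm <- confusion_matrix(rep(0:2, each = 10), rep(0:2, each = 10))
  m <- metrics_report(cm, mode = "macro")
  for (nm in c("accuracy", "precision", "sensitivity", "specificity",
               "f_measure", "mcc", "npv")) {
    expect_equal(m[[nm]], 1, info = nm)
  }
  expect_equal(m$fpr, 0)
  expect_equal(m$fnr, 0)
})

test_that("random guessing on balanced classes gives macro sensitivity near 1/3", {
  set.seed(2)
  n <- 10000
  yt <- rep(0:2, length.out = n)
  yp <- sample(0:2, n, replace = TRUE)
  m <- metrics_report(confusion_matrix(yt, yp))
  expect_lt(abs(m$sensitivity - 1 / 3), 0.03)
})

test_that("the report agrees with brute-force recomputation on random matrices", {
  set.seed(3)
  for (k in 1:1000) {
    cm <- random_cm()
    if (sum(cm) == 0) next
    per <- metrics_report(cm, mode = "per-class")
    mac <- metrics_report(cm, mode = "macro")
    want <- lapply(1:3, function(c_idx) metrics_oracle(cm, c_idx))
    for (nm in names(want[[1]])) {
      got <- per[[nm]]
      ref <- vapply(want, `[[`, numeric(1), nm)
      expect_equal(got, ref, tolerance = 1e-12)
      expect_equal(mac[[nm]], mean(ref), tolerance = 1e-12)
    }
    # binary identities hold for every one-vs-rest reduction
    expect_equal(per$fpr, 1 - per$specificity, tolerance = 1e-12)
    expect_equal(per$fnr, 1 - per$sensitivity, tolerance = 1e-12)
  }
})

test_that("MCC is symmetric under transposition in the binary case", {
  set.seed(4)
  for (k in 1:50) {
    cm <- matrix(sample.int(30, 4, replace = TRUE), 2, 2)
    m1 <- metrics_report(cm, mode = "binary", positive = 1L)
    m2 <- metrics_report(t(cm), mode = "binary", positive = 1L)
    expect_equal(m1$mcc, m2$mcc, tolerance = 1e-12)
  }
})

test_that("the alternative F variant and degenerate cells behave as documented", {
  cm <- matrix(c(35L, 10L, 5L, 50L), 2, 2, byrow = TRUE)
  std <- metrics_report(cm, mode = "binary", positive = 1L)
  alt <- metrics_report(cm, mode = "binary", positive = 1L,
                        f_variant = "product")
  expect_equal(alt$f_measure, std$f_measure / 2, tolerance = 1e-12)

  degenerate <- matrix(c(5L, 0L, 0L, 0L), 2, 2, byrow = TRUE)
  m <- metrics_report(degenerate, mode = "binary", positive = 1L)
  expect_equal(m$precision, 0)    # 0/0 cells defined as 0, no crash
  expect_error(metrics_report(matrix(0L, 3, 3)), "empty")
})

test_that("ROC curves sweep thresholds correctly and agree with pROC", {
  y <- c(0, 0, 0, 2, 2, 2)
  s <- c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9)
  r <- roc_points(y, s, class = 2)
  expect_equal(r$auc, 1)
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[1], 0)
  expect_equal(r$points$fpr[nrow(r$points)], 1)
  expect_equal(r$points$tpr[nrow(r$points)], 1)
  expect_true(all(diff(r$points$fpr) >= 0))

  set.seed(5)
  n <- 10000
  yt <- sample(c(0, 2), n, replace = TRUE)
  sc <- runif(n)                           # scores independent of labels
  expect_lt(abs(roc_points(yt, sc, class = 2)$auc - 0.5), 0.02)

  skip_if_not_installed("pROC")
  set.seed(6)
  yt <- sample(c(0, 2), 200, replace = TRUE)
  sc <- runif(200) + 0.3 * (yt == 2)
  ours <- roc_points(yt, sc, class = 2)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(yt, sc, levels = c(0, 2),
                                        direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-10)

  expect_error(roc_points(rep(2, 5), runif(5)), "positive and negative")
})
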