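test_that("confusion matrices count actual-by-predicted pairs", {
  cm <- confusion_matrix(c(1, 1, 2, 2, 2), c(1, 2, 2, 2, 1), labels = 1:2)
  expect_equal(unname(unclass(cm)), matrix(c(1L, 1L, 1L, 2L), 2,
                                           byrow = TRUE))
  perfect <- confusion_matrix(1:4, 1:4)
  expect_true(all(perfect[row(perfect) != col(perfect)] == 0))
  expect_equal(sum(diag(perfect)), 4L)
  set.seed(1)
  yt <- sample(1:3, 50, TRUE); yp <- sample(1:3, 50, TRUE)
  cm2 <- confusion_matrix(yt, yp)
  expect_equal(unname(colSums(cm2)), unname(as.vector(table(yp))))
  expect_error(confusion_matrix(1:3, c(1, 2, 9), labels = 1:3), "label")
})

test_that("per-class counts follow the column/row recipe and sum to the total", {
  cm <- confusion_matrix(rep(1:2, c(4, 6)),
                         c(1, 1, 1, 2, 1, 1, 2, 2, 2, 2), labels = 1:2)
  c1 <- per_class_counts(cm, 1)
  expect_equal(c1, list(TP = 3L, TN = 4L, FP = 2L, FN = 1L))
  expect_equal(c1$TP + c1$TN + c1$FP + c1$FN, sum(cm))

  set.seed(2)
  yt <- sample(1:4, 80, TRUE); yp <- sample(1:4, 80, TRUE)
  cmr <- confusion_matrix(yt, yp)
  tps <- vapply(1:4, function(k) per_class_counts(cmr, k)$TP, integer(1L))
  expect_equal(sum(tps), sum(diag(cmr)))
  for (k in 1:4) {
    cc <- per_class_counts(cmr, k)
    expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, 80L)
  }
})

test_that("metric ratios match their closed forms", {
  expect_equal(sensitivity(list(TP = 20, TN = 0, FP = 0, FN = 4)), 20 / 24)
  expect_equal(ppv(list(TP = 21, TN = 0, FP = 8, FN = 0)), 21 / 29)
  perfect <- list(TP = 5, TN = 10, FP = 0, FN = 0)
  expect_equal(sensitivity(perfect), 1)
  expect_equal(specificity(perfect), 1)
  expect_equal(misclassification_rate(perfect), 0)
  expect_warning(ppv(list(TP = 0, TN = 5, FP = 0, FN = 1)), "denominator")
  expect_equal(f1(0.727, 0.615), 2 * 0.727 * 0.615 / (0.727 + 0.615))
  expect_equal(f1(0, 0), 0)
})

test_that("micro-F1 equals overall accuracy in single-label classification", {
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(20:60, 1)
    k <- sample(2:6, 1)
    yt <- sample(seq_len(k), n, TRUE)
    yp <- sample(seq_len(k), n, TRUE)
    cm <- confusion_matrix(yt, yp, labels = seq_len(k))
    expect_equal(micro_f1(cm), sum(diag(cm)) / sum(cm), tolerance = 1e-12)
  }
})

test_that("macro F1 lies between the extreme per-class F1 scores", {
  set.seed(3)
  yt <- sample(1:4, 100, TRUE)
  yp <- ifelse(stats::runif(100) < 0.7, yt, sample(1:4, 100, TRUE))
  cm <- confusion_matrix(yt, yp)
  pcf <- mammotex:::per_class_f1(cm)
  expect_gte(macro_f1(cm), min(pcf))
  expect_lte(macro_f1(cm), max(pcf))
  expect_true(weighted_f1(cm) >= 0 && weighted_f1(cm) <= 1)
})

test_that("per-class sensitivity and specificity agree with an independent reference", {
  suppressWarnings(suppressMessages(requireNamespace("caret")))
  for (seed in 1:10) {
    set.seed(seed)
    yt <- factor(sample(1:3, 60, TRUE), levels = 1:3)
    yp <- factor(sample(1:3, 60, TRUE), levels = 1:3)
    cm <- confusion_matrix(as.integer(yt), as.integer(yp), labels = 1:3)
    ref <- caret::confusionMatrix(yp, yt)$byClass
    for (k in 1:3) {
      cc <- per_class_counts(cm, k)
      expect_equal(sensitivity(cc), unname(ref[k, "Sensitivity"]),
                   tolerance = 1e-12)
      expect_equal(specificity(cc), unname(ref[k, "Specificity"]),
                   tolerance = 1e-12)
    }
  }
})

test_that("the report tables carry one row per class plus pooled summaries", {
  set.seed(5)
  yt <- sample(1:8, 200, TRUE)
  yp <- ifelse(stats::runif(200) < 0.8, yt, sample(1:8, 200, TRUE))
  cm <- confusion_matrix(yt, yp, labels = 1:8)
  rep <- suppressWarnings(classification_report(cm))
  expect_equal(nrow(rep$per_class), 8L)
  expect_true(all(c("recall", "precision", "f1", "accuracy") %in%
                    names(rep$per_class)))
  expect_true(all(rep$pooled >= 0 & rep$pooled <= 1))
  pct <- suppressWarnings(classification_report(cm, percent = TRUE))
  expect_true(all(pct$pooled <= 100))
})
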