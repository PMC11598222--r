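test_that("confusion counts follow the positive-class definitions", {
  expect_equal(confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1)),
               c(TP = 1, TN = 1, FP = 1, FN = 1))
  expect_equal(confusion_counts(c(1, 0), c(1, 0)), c(TP = 1, TN = 1, FP = 0, FN = 0))
  expect_equal(confusion_counts(c(1, 0), c(0, 1)), c(TP = 0, TN = 0, FP = 1, FN = 1))
  expect_error(confusion_counts(c(1, 2), c(1, 1)), "\\{0, 1\\}")
})

test_that("binary metrics implement SE/SP/CCR/PPV/NPV with undefined as NA", {
  m <- binary_metrics(c(TP = 84, FN = 16, TN = 63, FP = 37))
  expect_equal(m$SE, 0.84)
  expect_equal(m$SP, 0.63)
  expect_equal(m$CCR, 0.735)
  m2 <- binary_metrics(c(TP = 0, FN = 5, TN = 5, FP = 0))
  expect_true(is.na(m2$PPV))   # TP + FP = 0: undefined, not zero
  expect_equal(m2$SP, 1)
})

test_that("macro one-vs-rest multiclass metrics match hand-counted tables", {
  m <- multiclass_metrics(c(0, 1, 2, 2), c(0, 2, 2, 2))
  expect_equal(m$SE, 2 / 3)
  expect_equal(m$SP, (1 + 1 + 0.5) / 3)
  expect_equal(m$CCR, 0.75)
  perfect <- multiclass_metrics(c(0, 1, 2), c(0, 1, 2))
  expect_equal(perfect$SE, 1)
  expect_equal(perfect$SP, 1)
  expect_equal(perfect$CCR, 1)
})

test_that("AUC equals the positive-outranks-negative pair probability", {
  expect_equal(auc_score(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(auc_score(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)
  # pairs: (0.9,0.8) win, (0.9,0.1) win, (0.7,0.8) loss, (0.7,0.1) win -> 3/4
  expect_equal(auc_score(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1)), 0.75)
  expect_true(is.na(auc_score(c(1, 1), c(0.2, 0.8))))
  # cross-check against an independent implementation on random instances
  skip_if_not_installed("pROC")
  set.seed(5)
  for (i in 1:10) {
    y <- rbinom(40, 1, 0.5)
    if (length(unique(y)) < 2) next
    p <- round(runif(40), 2)
    ref <- as.numeric(suppressMessages(pROC::auc(y, p, direction = "<")))
    expect_equal(auc_score(y, p), ref)
  }
})

test_that("metric computation agrees exactly with brute-force counting", {
  set.seed(11)
  for (i in 1:60) {
    n <- sample(5:200, 1)
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    call <- rbinom(n, 1, runif(1, 0.2, 0.8))
    got <- binary_metrics(confusion_counts(y, call))
    ref <- brute_binary_metrics(y, call)
    expect_identical(got, ref)
    if (!is.na(got$SE) && !is.na(got$SP)) {
      expect_equal(got$CCR, (got$SE + got$SP) / 2)
    }
  }
})
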