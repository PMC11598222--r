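test_that("geometric mean behaves at the corners", {
  expect_equal(gmean(1, 1), 1)
  expect_equal(gmean(0, 0.7), 0)
  expect_equal(gmean(0.5, 0.5), 0.5)
  expect_error(gmean(1.2, 0.5))
})

test_that("threshold selection maximizes the geometric mean with smallest-tie rule", {
  y <- c(1, 1, 0, 0)
  p <- c(0.9, 0.7, 0.2, 0.4)
  scan <- select_threshold(y, p)
  # gmean = 1 is reached everywhere in (0.4, 0.7]; the smallest candidate
  # attaining it is 0.5, which the tie rule selects
  expect_equal(attr(scan, "best_gmean"), 1)
  expect_equal(attr(scan, "pt"), 0.5)
  expect_equal(scan$gmean[scan$threshold == 0.7], 1)
  expect_setequal(scan$threshold, c(0.2, 0.4, 0.5, 0.7, 0.9))
  # perfectly inverted probabilities: a maximizer is still returned
  inv <- select_threshold(y, 1 - p)
  expect_true(is.finite(attr(inv, "best_gmean")))
  # all probabilities identical: every candidate ties, smallest wins
  same <- select_threshold(c(1, 0, 1), rep(0.3, 3))
  expect_equal(attr(same, "pt"), min(same$threshold))
  expect_error(select_threshold(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("threshold application is boundary-inclusive and monotone", {
  expect_equal(apply_threshold(c(0.5, 0.49), 0.5), c(1L, 0L))
  expect_equal(apply_threshold(c(0.2, 0.99), 1), c(0L, 0L))
  p <- runif(50)
  hi <- apply_threshold(p, 0.8)
  lo <- apply_threshold(p, 0.3)
  expect_true(all(lo >= hi))   # lowering PT never turns a 1 into a 0
})

test_that("selection matches the exhaustive oracle and never degrades below PT = 0.5", {
  set.seed(21)
  for (i in 1:60) {
    n <- sample(10:100, 1)
    y <- c(0, 1, rbinom(n - 2, 1, runif(1, 0.2, 0.8)))
    p <- round(runif(n), 3)
    scan <- select_threshold(y, p)
    ref <- brute_best_threshold(y, p)
    expect_equal(attr(scan, "pt"), ref$pt)
    expect_equal(attr(scan, "best_gmean"), ref$gmean)
    g_05 <- scan$gmean[scan$threshold == 0.5]
    expect_gte(attr(scan, "best_gmean"), g_05)
  }
})
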