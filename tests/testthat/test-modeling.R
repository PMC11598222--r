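test_that("fold plans partition indices, stratify classes and reproduce from seed", {
  f <- make_fold_plan(rep(c(0, 1), 5), k = 5, seed = 3)
  expect_equal(sort(unique(f)), 1:5)
  expect_equal(as.integer(table(f)), rep(2L, 5))
  expect_identical(unclass(f), unclass(make_fold_plan(rep(c(0, 1), 5), 5, 3)))
  # 8 positives / 2 negatives: the two negatives land in different folds
  y <- c(rep(1, 8), 0, 0)
  f2 <- suppressWarnings(make_fold_plan(y, k = 5, seed = 1))
  expect_equal(length(unique(f2[y == 0])), 2)
  expect_warning(make_fold_plan(y, k = 5, seed = 1), "fewer than k")
  # fold sizes never differ by more than one
  set.seed(2)
  y3 <- sample(0:2, 83, replace = TRUE)
  f3 <- make_fold_plan(y3, k = 5, seed = 9)
  expect_lte(diff(range(table(f3))), 1)
})

test_that("undersampling reduces the majority class to the runner-up size", {
  ds <- structure(list(task = "multiclass", scheme = "WES",
                       smiles = sprintf("S%02d", 1:24),
                       y = rep(c(0, 1, 2), times = c(5, 15, 4)),
                       log = data.frame(casrn = character(),
                                        action = character(),
                                        reason = character())),
                  class = "ss_dataset")
  out <- undersample_majority(ds, seed = 2)
  expect_equal(as.integer(table(out$y)), c(5L, 5L, 4L))
  # removed items all come from the majority class
  removed <- setdiff(ds$smiles, out$smiles)
  expect_true(all(ds$y[match(removed, ds$smiles)] == 1))
  # balanced input returned unchanged
  ds$y <- rep(0:2, 8)
  expect_identical(undersample_majority(ds, 2)$y, ds$y)
  # reproducible
  expect_identical(undersample_majority(ds, 5), undersample_majority(ds, 5))
})

test_that("training emits normalized probabilities and separates separable data", {
  set.seed(4)
  X <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 4), 30, 2))
  colnames(X) <- c("f1", "f2")
  y <- rep(c(0, 1), each = 30)
  for (alg in c("random_forest", "gradient_boosting", "svm")) {
    pred <- train_predictor(X, y, alg, seed = 6)
    P <- predict_prob(pred, X)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
    m <- binary_metrics(confusion_counts(y, as.integer(P[, "1"] >= 0.5)))
    expect_equal(m$CCR, 1)
    # deterministic given seed
    P2 <- predict_prob(train_predictor(X, y, alg, seed = 6), X)
    expect_equal(P, P2)
  }
  expect_error(train_predictor(X, rep(1, 60), "svm"), "single-class")
  expect_error(train_predictor(X, y, "nonsense"), "arg")
})

test_that("hyperparameter search never returns a configuration worse than the default", {
  set.seed(8)
  X <- matrix(rnorm(240), 60, 4)
  colnames(X) <- paste0("f", 1:4)
  y <- as.integer(X[, 1] + rnorm(60, 0, 0.5) > 0)
  one <- tune_hyperparameters(X, y, "random_forest", n_trials = 1, seed = 2)
  expect_equal(one$params[c("num_trees", "max_depth")],
               default_params("random_forest")[c("num_trees", "max_depth")])
  res <- tune_hyperparameters(X, y, "svm", n_trials = 6, seed = 2)
  expect_gte(res$objective, res$trace$objective[1])
  res2 <- tune_hyperparameters(X, y, "svm", n_trials = 6, seed = 2)
  expect_identical(res$trace, res2$trace)
})

test_that("cross-validation scores every compound exactly once out of fold", {
  ds <- small_binary()
  cv <- ss_crossval(ds, "ecfp4", "random_forest", seed = 5)
  expect_equal(nrow(cv$oof), length(ds$smiles))
  expect_true(all(!is.na(cv$oof$prob_1)))
  expect_equal(sort(unique(cv$oof$fold)), 1:5)
  # CCR identity holds on the pooled report
  m <- cv$pooled
  expect_equal(m$CCR, (m$SE + m$SP) / 2)
  expect_equal(cv$coverage, 100 * mean(cv$oof$in_ad))
  # calibrated PT comes from the pooled out-of-fold scan
  expect_equal(cv$pt, attr(cv$calibration, "pt"))
})

test_that("y-randomization returns one report per round near chance level", {
  ds <- small_binary()
  yr <- y_randomize(ds, "ecfp4", "random_forest", seed = 5, rounds = 3)
  expect_length(yr$reports, 3)
  expect_true(all(yr$ccr > 0.2 & yr$ccr < 0.8))
  for (m in yr$reports) expect_equal(m$CCR, (m$SE + m$SP) / 2)
})
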