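test_that("forest attributions are exactly additive on the probability scale", {
  m <- small_model()
  X <- m$pipeline$train_matrix[1:10, , drop = FALSE]
  att <- feature_attributions(m, X)
  P <- predict_prob(m$predictor, X)[, "1"]
  expect_lt(max(abs(att$base + rowSums(att$phi) - P)), 1e-10)
  expect_equal(att$fx, unname(P))
  expect_error(feature_attributions(m, matrix(0, 1, 3)), "mismatch")
})

test_that("a single-feature model concentrates attribution on that feature", {
  set.seed(14)
  X <- matrix(rbinom(400, 1, 0.5), 100, 4)
  colnames(X) <- paste0("b", 1:4)
  y <- X[, 2]
  ds <- structure(list(task = "binary", scheme = "toy",
                       smiles = sprintf("T%03d", 1:100), y = y,
                       log = data.frame()), class = "ss_dataset")
  # fit the predictor directly in the toy feature space
  pred <- train_predictor(X, y, "random_forest", seed = 2)
  fake <- structure(list(task = "binary", feature_kind = "ecfp4",
                         algorithm = "random_forest", predictor = pred,
                         classes = pred$classes, seed = 2,
                         pipeline = structure(list(kind = "ecfp4",
                                                   selections = list(),
                                                   scaler = NULL,
                                                   train_matrix = X),
                                              class = "ss_feature_pipeline")),
                    class = "ss_model")
  att <- feature_attributions(fake, X[1:20, ])
  mass <- colMeans(abs(att$phi))
  expect_equal(which.max(mass), 2L)
  expect_gt(mass[2], 10 * max(mass[-2]))
})

test_that("sampling and boosting attributions keep exact additivity on their scales", {
  set.seed(15)
  X <- matrix(rnorm(300), 50, 6)
  colnames(X) <- paste0("f", 1:6)
  y <- as.integer(X[, 1] > 0)
  pipe <- structure(list(kind = "descriptors", selections = list(),
                         scaler = NULL, train_matrix = X),
                    class = "ss_feature_pipeline")
  for (alg in c("svm", "gradient_boosting")) {
    pred <- train_predictor(X, y, alg, seed = 3)
    fake <- structure(list(task = "binary", feature_kind = "descriptors",
                           algorithm = alg, predictor = pred,
                           classes = pred$classes, seed = 3, pipeline = pipe),
                      class = "ss_model")
    att <- feature_attributions(fake, X[1:5, ], n_perm = 10)
    resid <- abs(att$base + rowSums(att$phi) - att$fx)
    expect_lt(max(resid), 1e-6)
    if (att$scale == "probability") {
      P <- predict_prob(pred, X[1:5, ])[, "1"]
      expect_lt(max(abs(att$fx - P)), 1e-9)
    }
  }
})

test_that("every on-bit belongs to at least one atom environment", {
  for (smi in c("CCCCCC=O", "NS(=O)(=O)c1ccccc1", "OCC(O)CCC")) {
    ac <- atom_contributions(small_model(), smi)
    covered <- sort(unique(unlist(ac$atom_bits)))
    expect_equal(covered, sort(unlist(ac$on_bits)))
    expect_equal(length(ac$weight), length(ac$symbol))
    if (any(ac$weight != 0)) expect_equal(max(abs(ac$weight)), 1)
  }
})

test_that("alert atoms dominate the contribution map of an alert-trained model", {
  m <- small_model()
  ac <- atom_contributions(m, "CCCCCC=O")
  # aldehyde group: carbonyl carbon + oxygen + alpha carbon
  alert_atoms <- which(ac$symbol == "O" | seq_along(ac$symbol) >= 6)
  expect_gt(mean(ac$weight[alert_atoms]), mean(ac$weight[-alert_atoms]))
  # invariance under input SMILES reordering
  ac2 <- atom_contributions(m, "O=CCCCCC")
  expect_equal(ac$weight, ac2$weight)
  expect_error(atom_contributions(m, "not_smiles"), "standardize")
})

test_that("descriptor models refuse contribution maps", {
  ds <- small_binary()
  md <- ss_fit(ds, "descriptors", "random_forest", seed = 3,
               calibrate = FALSE)
  expect_error(atom_contributions(md, "CCO"), "fingerprint")
})

test_that("contribution maps render to a deterministic non-empty depiction", {
  ac <- atom_contributions(small_model(), "CCCCCC=O")
  f1 <- tempfile(fileext = ".svg")
  f2 <- tempfile(fileext = ".svg")
  render_contribution_map(ac, f1)
  render_contribution_map(ac, f2)
  expect_gt(file.info(f1)$size, 500)
  expect_identical(readLines(f1), readLines(f2))
  # all-zero map: no highlights, still renders
  ac$weight[] <- 0
  f3 <- tempfile(fileext = ".svg")
  res <- chem_backend("depict", list(smiles = ac$std_smiles,
                                     weights = as.list(ac$weight),
                                     out_file = f3))
  expect_equal(res$n_highlighted, 0)
  expect_gt(file.info(f3)$size, 100)
})
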