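test_that("fingerprints are fixed-length, deterministic and structure-pure", {
  X <- ecfp4(c("CCO", "OCC", "c1ccccc1"))
  expect_equal(ncol(X), 2048)
  expect_true(all(X %in% c(0, 1)))
  expect_true(sum(X[1, ]) >= 1)
  expect_identical(X[1, ], X[2, ])        # same molecule, different SMILES
  expect_true(any(X[1, ] != X[3, ]))      # ethanol vs benzene differ
  expect_identical(ecfp4("CCO"), ecfp4("CCO"))
  expect_error(ecfp4("xx("), "invalid structure")
})

test_that("MACCS keys have 167 positions with index 0 unused", {
  X <- maccs(c("C", "CCO", "c1ccccc1"))
  expect_equal(ncol(X), 167)
  expect_equal(unname(X[, 1]), c(0, 0, 0))   # key 0 by convention unused
  expect_true(sum(X["C", ]) >= 1)            # methane has defined keys
  expect_true(any(X["CCO", ] != X["c1ccccc1", ]))
})

test_that("descriptor block is row-pure and staged for variance filtering", {
  X <- descriptor_block(c("CCO", "CCO", "CCC"))
  expect_identical(X[1, ], X[2, ])
  sel <- drop_nonfinite(X)
  Xc <- apply_selection(sel, X)
  expect_true(all(is.finite(Xc)))
  # a constant column survives the block but dies in the variance filter
  Xc2 <- cbind(Xc, const = 5)
  vf <- variance_filter(Xc2, 0.01)
  expect_false(ncol(Xc2) %in% vf$indices)
})

test_that("variance filter retains exactly features above the threshold", {
  n <- 200
  rare <- c(1, rep(0, n - 1))               # p = 0.005, var = p(1-p) < 0.01
  alt <- rep(c(0, 1), n / 2)                # var = 0.25
  X <- cbind(zero = 0, rare = rare, alt = alt)
  sel <- variance_filter(X, 0.01)
  expect_equal(sel$indices, 3L)
  # population variance agrees with the brute-force definition
  expect_equal(mean((rare - mean(rare))^2), 0.005 * 0.995)
  expect_error(variance_filter(cbind(a = rep(0, 5)), 0.01), "no informative")
})

test_that("recursive feature elimination keeps label-defining features", {
  set.seed(9)
  X <- cbind(signal = rep(c(0, 1), each = 30),
             matrix(rnorm(60 * 9), 60, 9,
                    dimnames = list(NULL, paste0("noise", 1:9))))
  y <- X[, "signal"]
  sel <- rfe_select(X, y, n_target = 1, seed = 4)
  expect_equal(sel$indices, 1L)
  expect_equal(rfe_select(X, y, n_target = 10, seed = 4)$indices, 1:10)
  expect_error(rfe_select(X, y, n_target = 11, seed = 4), "exceeds")
  # deterministic given seed
  expect_identical(rfe_select(X, y, 3, seed = 4)$indices,
                   rfe_select(X, y, 3, seed = 4)$indices)
})

test_that("min-max scaling is an affine map fitted on the training fold only", {
  train <- cbind(a = c(2, 4), b = c(3, 3))
  sc <- fit_minmax(train)
  out <- apply_minmax(sc, train)
  expect_equal(unname(out[, "a"]), c(0, 1))
  expect_equal(unname(out[, "b"]), c(0, 0))     # constant feature -> 0
  # external rows may exceed [0, 1]: no clipping
  expect_equal(unname(apply_minmax(sc, cbind(a = 5, b = 7))[, "a"]), 1.5)
  expect_error(apply_minmax(sc, matrix(1, 1, 3)), "mismatch")
  # training rows always land inside [0, 1]
  set.seed(1)
  Xr <- matrix(rnorm(80), 20, 4)
  sr <- fit_minmax(Xr)
  expect_true(all(apply_minmax(sr, Xr) >= 0 & apply_minmax(sr, Xr) <= 1))
})

test_that("fitted pipeline state depends on the training fold only", {
  sim <- small_sim()
  smi <- unique(standardize_records(sim$records)$std_smiles)
  smi <- smi[!is.na(smi)][1:40]
  y <- rep(c(0, 1), 20)
  p1 <- fit_feature_pipeline(smi, "ecfp4", y = y)
  p2 <- fit_feature_pipeline(smi, "ecfp4", y = y)
  expect_identical(p1$selections$variance$indices,
                   p2$selections$variance$indices)
  # scoring held-out rows does not mutate the fitted state
  before <- p1$selections$variance$indices
  invisible(apply_feature_pipeline(p1, c("CCOC(=O)CC", "c1ccncc1")))
  expect_identical(p1$selections$variance$indices, before)
})
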