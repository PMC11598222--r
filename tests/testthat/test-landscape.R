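test_that("normalized distances form a unit-scaled metric", {
  X <- rbind(a = c(0, 0), b = c(0, 0), c = c(3, 4), d = c(1, 1))
  D <- normalized_distances(X)
  expect_equal(D["a", "b"], 0)
  expect_equal(max(D), 1)
  expect_equal(D, t(D))
  expect_equal(diag(D), setNames(rep(0, 4), rownames(X)))
  expect_error(normalized_distances(X[1, , drop = FALSE]), "at least 2")
  # triangle inequality on random instances
  set.seed(41)
  Dr <- normalized_distances(matrix(rnorm(30), 10, 3))
  for (i in 1:10) for (j in 1:10) for (k in 1:10) {
    expect_lte(Dr[i, j], Dr[i, k] + Dr[k, j] + 1e-12)
  }
})

test_that("ROGI is zero for constant activity and affine invariant", {
  set.seed(42)
  D <- normalized_distances(matrix(rnorm(24), 12, 2))
  expect_equal(rogi(D, rep(3.7, 12))$rogi, 0)
  a <- rnorm(12)
  expect_equal(rogi(D, a)$rogi, rogi(D, 5 * a + 2)$rogi, tolerance = 1e-12)
  # constant distances with varying activity: maximal roughness with warning
  Dc <- matrix(1, 6, 6); diag(Dc) <- 0
  expect_warning(r <- rogi(Dc, 1:6), "maximally rough")
  a6 <- (1:6 - 1) / 5
  expect_equal(r$rogi, 2 * sqrt(mean((a6 - mean(a6))^2)))
})

test_that("ROGI equals the naive merge-enumeration oracle on tiny instances", {
  set.seed(43)
  for (i in 1:8) {
    n <- sample(5:10, 1)
    D <- normalized_distances(matrix(rnorm(n * 3), n, 3))
    a <- rnorm(n)
    expect_equal(rogi(D, a)$rogi, brute_rogi(D, a), tolerance = 1e-9)
  }
})

test_that("shuffled activity is rougher than distance-correlated smooth activity", {
  set.seed(44)
  hits <- 0
  reps <- 20
  for (r in 1:reps) {
    X <- matrix(rnorm(40), 20, 2)
    D <- normalized_distances(X)
    smooth <- X[, 1] + 0.1 * rnorm(20)   # activity tracks the geometry
    shuffled <- sample(smooth)
    if (rogi(D, shuffled)$rogi >= rogi(D, smooth)$rogi) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.9)
})

test_that("classical MDS reproduces simple exact configurations", {
  D2 <- as.matrix(dist(rbind(c(0, 0), c(3, 4))))
  co <- mds_embed(D2, seed = 1)
  expect_equal(as.numeric(dist(co)), 5, tolerance = 1e-9)
  # equilateral triangle: all embedded pairs equal
  D3 <- matrix(1, 3, 3); diag(D3) <- 0
  co3 <- mds_embed(D3, seed = 1)
  pw <- as.numeric(dist(co3))
  expect_lt(diff(range(pw)), 1e-6)
  expect_identical(mds_embed(D3, seed = 1), mds_embed(D3, seed = 1))
})

test_that("activity grids interpolate within range and through the data", {
  set.seed(45)
  co <- cbind(z1 = runif(15), z2 = runif(15))
  a <- rnorm(15)
  g <- activity_grid(co, a, resolution = 12)
  expect_equal(dim(g$z), c(12, 12))
  expect_true(all(g$z >= min(a) - 1e-9 & g$z <= max(a) + 1e-9))
  expect_equal(interpolate_activity(co, a, co), a)
  gc <- activity_grid(co, rep(2, 15), resolution = 5)
  expect_true(all(abs(gc$z - 2) < 1e-12))
  line <- cbind(1:5, 2 * (1:5) + 1)
  expect_error(activity_grid(line, 1:5), "collinear")
})

test_that("chemical-space grouping separates structural families order-invariantly", {
  alkanes <- c("CCCCC", "CCCCCC", "CCCCCCC", "CCCCCCCC", "CC(C)CC",
               "CC(C)CCC", "CCC(C)CC", "CC(C)(C)CC", "CCCCCCCCC", "CC(C)CCCC")
  phenols <- c("Oc1ccccc1O", "Oc1ccc(O)cc1", "Oc1cccc(O)c1", "Oc1ccc(O)c(O)c1",
               "Oc1cc(O)cc(O)c1", "Oc1ccccc1", "Cc1cc(O)ccc1O",
               "Oc1ccc2ccccc2c1", "Oc1ccc(Cc2ccc(O)cc2)cc1", "Oc1cc(O)c(O)cc1O")
  g <- chemspace_grouping(c(alkanes, phenols), seed = 42)
  fam <- rep(c("alk", "phe"), each = 10)
  real <- g$group[g$group > 0]
  expect_gte(length(unique(real)), 2)
  # family purity: each non-noise group is dominated by one family
  for (grp in unique(real)) {
    members <- fam[g$group == grp]
    expect_gte(max(table(members)) / length(members), 0.9)
  }
  # permuting the input gives the same partition
  g2 <- chemspace_grouping(rev(c(alkanes, phenols)), seed = 42)
  expect_identical(g$group, rev(g2$group))
  expect_error(chemspace_grouping(alkanes[1:5], seed = 1), "too few")
})
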