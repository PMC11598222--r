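# Shared fixtures, built once per test run and memoised. Everything is
# generated in code; nothing is read from disk.

.fixture_env <- new.env(parent = emptyenv())

.memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small synthetic table for fast unit tests
small_sim <- function() {
  .memo("small_sim", function() {
    simulate_compound_table(synthetic_config(n = 120, seed = 7), doses = FALSE)
  })
}

small_binary <- function() {
  .memo("small_binary", function() {
    curate_dataset(small_sim()$records, "binary", "WES")
  })
}

# quick alert-trained fingerprint model shared by interpretation tests
small_model <- function() {
  .memo("small_model", function() {
    ss_fit(small_binary(), "ecfp4", "random_forest", seed = 3,
           calibrate = FALSE)
  })
}

# study-scale synthetic set (the generator's default conditions)
study_sim <- function() {
  .memo("study_sim", function() simulate_compound_table(synthetic_config()))
}

study_binary <- function() {
  .memo("study_binary", function() {
    curate_dataset(study_sim()$records, "binary", "WES")
  })
}

# brute-force binary metrics straight from the definitions, as loops
brute_binary_metrics <- function(y, call) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(y)) {
    if (y[i] == 1 && call[i] == 1) tp <- tp + 1L
    if (y[i] == 0 && call[i] == 0) tn <- tn + 1L
    if (y[i] == 0 && call[i] == 1) fp <- fp + 1L
    if (y[i] == 1 && call[i] == 0) fn <- fn + 1L
  }
  se <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  list(SE = se, SP = sp, CCR = (se + sp) / 2,
       PPV = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       NPV = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
}

# exhaustive threshold scan oracle: every observed probability plus 0.5
brute_best_threshold <- function(y, p) {
  cand <- sort(unique(c(p, 0.5)))
  best_t <- NA_real_; best_g <- -1
  for (t in cand) {
    call <- as.integer(p >= t)
    se <- sum(call == 1 & y == 1) / sum(y == 1)
    sp <- sum(call == 0 & y == 0) / sum(y == 0)
    g <- sqrt(se * sp)
    if (g > best_g) { best_g <- g; best_t <- t }
  }
  list(pt = best_t, gmean = best_g)
}

# independent complete-linkage ROGI oracle for tiny instances: naive
# agglomeration over all merge thresholds, trapezoidal integration
brute_rogi <- function(D, activity) {
  n <- length(activity)
  rng <- max(activity) - min(activity)
  a <- if (rng > 0) (activity - min(activity)) / rng else rep(0, n)
  wsd <- function(vals, sizes) {
    w <- sizes / sum(sizes)
    mu <- sum(w * vals)
    sqrt(sum(w * (vals - mu)^2))
  }
  # naive agglomeration: always merge the closest pair (complete linkage),
  # recording the partition sequence and merge heights
  groups <- as.list(seq_len(n))
  partitions <- list(groups)
  merge_h <- numeric(0)
  while (length(groups) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(groups)) {
      for (j in seq_along(groups)) {
        if (j <= i) next
        dmax <- max(D[groups[[i]], groups[[j]], drop = FALSE])
        if (dmax < best_d) { best_d <- dmax; best <- c(i, j) }
      }
    }
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
    merge_h <- c(merge_h, best_d)
    partitions[[length(partitions) + 1]] <- groups
  }
  heights <- sort(unique(c(0, pmin(pmax(merge_h, 0), 1), 1)))
  sigma_at <- function(t) {
    k <- sum(merge_h <= t)  # partition after all merges at height <= t
    gr <- partitions[[k + 1]]
    means <- vapply(gr, function(g) mean(a[g]), 0)
    sizes <- vapply(gr, length, 0L)
    wsd(means, sizes)
  }
  sig <- vapply(heights, sigma_at, 0)
  s0 <- wsd(a, rep(1, n))
  integrand <- s0 - sig
  2 * sum(diff(heights) * (head(integrand, -1) + integrand[-1]) / 2)
}
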