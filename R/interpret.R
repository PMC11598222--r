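# Model interpretation: additive per-feature attributions and atom-level
# fragment contribution maps obtained by zeroing the fingerprint bits whose
# circular environments contain each atom.

# apply a fitted feature pipeline to an already-featurized full-width matrix
.apply_pipeline_matrix <- function(pipeline, X) {
  for (sel in pipeline$selections) X <- apply_selection(sel, X)
  if (!is.null(pipeline$scaler)) X <- apply_minmax(pipeline$scaler, X)
  X
}

# ---- tree path attribution (random forest) --------------------------------

# Per-tree arrays + internal node values (training-set weighted averages of
# the stored terminal-node probabilities); contributions telescope exactly to
# leaf value - root value, so base + sum(phi) equals the forest probability.
.rf_tree_tables <- function(rf, X_train, target_level) {
  lapply(seq_len(rf$num.trees), function(t) {
    ti <- ranger::treeInfo(rf, t)
    pred_col <- paste0("pred.", target_level)
    if (!pred_col %in% names(ti)) {
      # column naming differs across ranger versions; fall back by suffix
      pc <- grep("^pred", names(ti), value = TRUE)
      idx <- match(target_level, sub("^pred(iction)?\\.", "", pc))
      if (is.na(idx)) stop("cannot locate prediction column for class ",
                           target_level)
      pred_col <- pc[idx]
    }
    left <- ti$leftChild + 1L
    right <- ti$rightChild + 1L
    splitvar <- ti$splitvarID + 1L
    splitval <- ti$splitval
    leaf <- ti$terminal
    vleaf <- ti[[pred_col]]
    n_nodes <- nrow(ti)
    # route training rows to leaves (level-synchronous)
    cur <- rep(1L, nrow(X_train))
    repeat {
      open <- which(!leaf[cur])
      if (!length(open)) break
      cc <- cur[open]
      goes_left <- X_train[cbind(open, splitvar[cc])] <= splitval[cc]
      cur[open] <- ifelse(goes_left, left[cc], right[cc])
    }
    counts <- tabulate(cur, nbins = n_nodes)
    vsum <- numeric(n_nodes)
    vsum[leaf] <- counts[leaf] * ifelse(is.na(vleaf[leaf]), 0, vleaf[leaf])
    # children always have larger nodeIDs: aggregate bottom-up
    for (node in rev(which(!leaf))) {
      counts[node] <- counts[left[node]] + counts[right[node]]
      vsum[node] <- vsum[left[node]] + vsum[right[node]]
    }
    value <- ifelse(counts > 0, vsum / pmax(counts, 1), 0)
    value[leaf] <- ifelse(is.na(vleaf[leaf]), 0, vleaf[leaf])
    list(left = left, right = right, splitvar = splitvar,
         splitval = splitval, leaf = leaf, value = value)
  })
}

.rf_attributions <- function(rf, X_train, X, target_level) {
  trees <- .rf_tree_tables(rf, X_train, target_level)
  n_feat <- ncol(X)
  base <- mean(vapply(trees, function(tr) tr$value[1], 0))
  phi <- matrix(0, nrow(X), n_feat)
  fx <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    x <- X[i, ]
    acc <- numeric(n_feat)
    leaf_sum <- 0
    for (tr in trees) {
      node <- 1L
      while (!tr$leaf[node]) {
        nxt <- if (x[tr$splitvar[node]] <= tr$splitval[node]) tr$left[node]
               else tr$right[node]
        acc[tr$splitvar[node]] <- acc[tr$splitvar[node]] +
          (tr$value[nxt] - tr$value[node])
        node <- nxt
      }
      leaf_sum <- leaf_sum + tr$value[node]
    }
    phi[i, ] <- acc / length(trees)
    fx[i] <- leaf_sum / length(trees)
  }
  list(phi = phi, base = base, fx = fx, scale = "probability")
}

# ---- permutation sampling attribution (kernel models) ---------------------

# Antithetic-free permutation sampling: over random feature orderings, the
# marginal change from switching each feature from a background row to the
# explained row. Sums telescope, so base + sum(phi) = f(x) exactly.
.sampling_attributions <- function(predict_fun, X_bg, X, n_perm = 20,
                                   seed = 1) {
  n_feat <- ncol(X)
  phi <- matrix(0, nrow(X), n_feat)
  base <- numeric(nrow(X))
  fx <- numeric(nrow(X))
  rng <- .restore_seed_state(); on.exit(rng())
  for (i in seq_len(nrow(X))) {
    set.seed(seed + i)
    x <- X[i, ]
    acc <- numeric(n_feat)
    b_vals <- numeric(n_perm)
    for (s in seq_len(n_perm)) {
      b <- X_bg[sample(nrow(X_bg), 1), ]
      ord <- sample(n_feat)
      # rows: background, then cumulatively switched to x along ord
      Z <- matrix(rep(b, n_feat + 1), nrow = n_feat + 1, byrow = TRUE)
      for (j in seq_len(n_feat)) {
        Z[(j + 1):(n_feat + 1), ord[j]] <- x[ord[j]]
      }
      f <- predict_fun(Z)
      acc[ord] <- acc[ord] + diff(f)
      b_vals[s] <- f[1]
    }
    phi[i, ] <- acc / n_perm
    base[i] <- mean(b_vals)
    fx[i] <- base[i] + sum(phi[i, ])
  }
  list(phi = phi, base = base, fx = fx, scale = "probability")
}

#' Additive per-feature attributions
#'
#' Decomposes each prediction into additive per-feature contributions.
#' Random-forest models are explained exactly by tree-path decomposition on
#' the probability scale (`base + sum(phi)` equals the predicted probability
#' to machine precision). Gradient-boosting models use the booster's exact
#' tree contributions on the log-odds scale. SVM models are explained by
#' seeded permutation sampling against training background rows; the
#' telescoping construction keeps additivity exact while the per-feature
#' values are sampling approximations.
#'
#' @param model An `ss_model`.
#' @param X Feature rows in the model's (post-pipeline) feature space;
#'   a vector for a single compound.
#' @param target_class Class whose probability is attributed (default the
#'   positive class `"1"` for binary models, the highest class otherwise).
#' @param n_perm Permutations per row for the sampling explainer.
#' @return An `ss_attribution`: list with `phi` (rows x features), `base`,
#'   `fx` (reconstructed outputs) and `scale`.
#' @export
feature_attributions <- function(model, X, target_class = NULL, n_perm = 20) {
  stopifnot(inherits(model, "ss_model"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  n_feat <- ncol(model$pipeline$train_matrix)
  if (ncol(X) != n_feat) {
    stop("feature mismatch: model space has ", n_feat, " features, rows have ",
         ncol(X))
  }
  if (is.null(target_class)) {
    target_class <- if (model$task == "binary") "1"
                    else max(model$classes)
  }
  target_class <- as.character(target_class)
  alg <- model$algorithm
  res <- if (alg == "random_forest") {
    .rf_attributions(model$predictor$fit, model$pipeline$train_matrix, X,
                     target_class)
  } else if (alg == "gradient_boosting" && length(model$classes) == 2) {
    dm <- xgboost::xgb.DMatrix(X, nthread = 1)
    contrib <- predict(model$predictor$fit, dm, predcontrib = TRUE)
    list(phi = contrib[, -ncol(contrib), drop = FALSE],
         base = contrib[, ncol(contrib)],
         fx = rowSums(contrib), scale = "log_odds")
  } else {
    pf <- function(Z) predict_prob(model$predictor, Z)[, target_class]
    bg <- model$pipeline$train_matrix
    if (nrow(bg) > 50) {
      rng <- .restore_seed_state()
      set.seed(model$seed)
      bg <- bg[sample(nrow(bg), 50), , drop = FALSE]
      rng()
    }
    .sampling_attributions(pf, bg, X, n_perm = n_perm, seed = model$seed)
  }
  res$target_class <- target_class
  structure(res, class = "ss_attribution")
}

#' @export
print.ss_attribution <- function(x, ...) {
  cat("Feature attributions for", nrow(x$phi), "row(s) on the", x$scale,
      "scale (target class", paste0(x$target_class, ")"), "\n")
  cat("  max |residual| of additivity:",
      format(max(abs(x$base + rowSums(x$phi) - x$fx)), digits = 3), "\n")
  invisible(x)
}

# ---- atom-level fragment contribution maps --------------------------------

#' Atom-level fragment contribution map
#'
#' For each atom of a molecule, identifies the fingerprint bits whose
#' circular environments contain that atom (hash-collision-shared bits belong
#' to every owning atom), zeroes them, and records the predicted probability
#' difference `P(full) - P(bits removed)`. Positive weights mark atoms whose
#' substructures push the prediction toward sensitization. Weights are
#' normalized by the maximum absolute value per molecule, and are invariant
#' to the input SMILES atom ordering (the structure is canonicalized first).
#'
#' @param model A fingerprint-based (`ecfp4`/`morgan2`) binary or multiclass
#'   `ss_model`; descriptor models error.
#' @param smiles A single SMILES string.
#' @param target_class Class whose probability is tracked (defaults as in
#'   [feature_attributions()]).
#' @return An `ss_atom_contrib`: data.frame-like list with `std_smiles`,
#'   per-atom `symbol`, normalized `weight`, raw `delta`, and `p_full`.
#' @export
atom_contributions <- function(model, smiles, target_class = NULL) {
  stopifnot(inherits(model, "ss_model"), length(smiles) == 1)
  if (!model$feature_kind %in% c("ecfp4", "morgan2")) {
    stop("contribution maps require fingerprint models ",
         "(circular fingerprints with bit-atom environments)")
  }
  if (is.null(target_class)) {
    target_class <- if (model$task == "binary") "1" else max(model$classes)
  }
  target_class <- as.character(target_class)
  std <- standardize_structure(smiles)
  if (std$status[1] != "ok") stop("cannot standardize structure: ", smiles)
  smi <- std$std_smiles[1]
  info <- .cached_backend("bit_atoms", smi)[[1]]
  n_atoms <- info$n_atoms
  on_bits <- unlist(info$on_bits)
  full <- numeric(2048)
  full[on_bits + 1L] <- 1
  rows <- matrix(rep(full, n_atoms + 1L), nrow = n_atoms + 1L, byrow = TRUE)
  for (a in seq_len(n_atoms)) {
    bits <- unlist(info$atom_bits[[a]])
    if (length(bits)) rows[a + 1L, bits + 1L] <- 0
  }
  Xp <- .apply_pipeline_matrix(model$pipeline, rows)
  p <- predict_prob(model$predictor, Xp)[, target_class]
  delta <- p[1] - p[-1]
  w <- if (any(delta != 0)) delta / max(abs(delta)) else delta
  structure(list(std_smiles = smi,
                 symbol = vapply(info$symbols, identity, ""),
                 weight = as.numeric(w), delta = as.numeric(delta),
                 p_full = p[1], target_class = target_class,
                 atom_bits = info$atom_bits, on_bits = on_bits),
            class = "ss_atom_contrib")
}

#' @export
print.ss_atom_contrib <- function(x, ...) {
  cat("Atom contribution map for", x$std_smiles, "\n")
  cat("  P(class ", x$target_class, ") = ", format(x$p_full, digits = 3),
      "\n", sep = "")
  df <- data.frame(atom = seq_along(x$symbol) - 1L, symbol = x$symbol,
                   weight = round(x$weight, 3))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.ss_atom_contrib <- function(x, ...) {
  data.frame(atom = seq_along(x$symbol) - 1L, symbol = x$symbol,
             weight = x$weight, delta = x$delta, stringsAsFactors = FALSE)
}

#' Render an atom contribution map to an SVG depiction
#'
#' Draws the molecule with a diverging color scale: atoms with positive
#' weights (toward sensitization) in green, negative in purple, intensity
#' proportional to the normalized weight. Deterministic for fixed input.
#'
#' @param map An `ss_atom_contrib` from [atom_contributions()].
#' @param file Output path (`.svg`).
#' @return The output path, invisibly.
#' @export
render_contribution_map <- function(map, file) {
  stopifnot(inherits(map, "ss_atom_contrib"))
  chem_backend("depict", list(smiles = map$std_smiles,
                              weights = as.list(map$weight),
                              out_file = file))
  invisible(file)
}
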