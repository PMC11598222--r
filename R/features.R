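# Featurization (fingerprints + physicochemical descriptor block),
# unsupervised and supervised feature selection, fold-isolated min-max
# scaling, and the composed per-fold feature pipeline.

FEATURE_KINDS <- c("ecfp4", "morgan2", "maccs", "descriptors")

.fp_length <- function(kind) switch(kind, ecfp4 = 2048L, morgan2 = 2048L,
                                    maccs = 167L)

#' Compute a feature matrix for a set of standardized structures
#'
#' Kinds: `"ecfp4"` (2048-bit extended-connectivity fingerprint, diameter 4),
#' `"morgan2"` (alias: radius-2 Morgan, identical bits), `"maccs"` (167
#' structural keys, position 0 unused by convention) and `"descriptors"`
#' (RDKit's 2-D physicochemical descriptor block, ~210 continuous values;
#' non-finite entries are returned as `NA` and handled downstream by
#' [drop_nonfinite()]).
#'
#' Featurization is a pure function of the canonical structure: two SMILES of
#' the same molecule give identical rows.
#'
#' @param smiles Character vector of standardized SMILES.
#' @param kind One of `r paste0('"', FEATURE_KINDS, '"', collapse = ", ")`.
#' @return Numeric matrix (compounds x features) with `rownames = smiles` and
#'   named columns; attribute `kind` records the feature kind.
#' @export
feature_matrix <- function(smiles, kind = FEATURE_KINDS) {
  kind <- match.arg(kind)
  stopifnot(length(smiles) >= 1)
  smiles <- as.character(smiles)
  if (kind == "descriptors") {
    keys <- vapply(smiles, function(s) .cache_key("descrow", "", s), "")
    res <- .cache_get(keys)
    miss <- which(vapply(res, is.null, TRUE))
    if (length(miss)) {
      out <- chem_backend("descriptors", list(smiles = as.list(smiles[miss])))
      nm <- unlist(out$names)
      rows <- lapply(out$rows, function(r) {
        if (is.null(r)) return(NULL)
        vapply(r, function(v) if (is.null(v)) NA_real_ else as.numeric(v), 0)
      })
      rows <- lapply(rows, function(r) { if (!is.null(r)) names(r) <- nm; r })
      .cache_put(vapply(smiles[miss], function(s) .cache_key("descrow", "", s), ""),
                 rows)
      res[miss] <- rows
    }
    bad <- vapply(res, is.null, TRUE)
    if (any(bad)) {
      stop("invalid structure(s) for descriptor calculation: ",
           paste(smiles[bad], collapse = ", "))
    }
    X <- do.call(rbind, res)
    rownames(X) <- smiles
  } else {
    n_bits <- .fp_length(kind)
    res <- .cached_backend("fingerprints", smiles, extra_key = kind,
                           payload_extra = list(kind = kind))
    bad <- vapply(res, is.null, TRUE)
    if (any(bad)) {
      stop("invalid structure(s) for fingerprinting: ",
           paste(smiles[bad], collapse = ", "))
    }
    X <- matrix(0, nrow = length(smiles), ncol = n_bits,
                dimnames = list(smiles, paste0("bit_", seq_len(n_bits) - 1L)))
    for (i in seq_along(res)) {
      on <- unlist(res[[i]])
      if (length(on)) X[i, on + 1L] <- 1
    }
  }
  attr(X, "kind") <- kind
  X
}

#' 2048-bit ECFP4 fingerprint
#'
#' @param smiles Character vector of standardized SMILES.
#' @return Binary matrix, 2048 columns (`bit_0` ... `bit_2047`).
#' @export
ecfp4 <- function(smiles) feature_matrix(smiles, "ecfp4")

#' 167-key MACCS structural fingerprint
#'
#' Key 0 is unused by convention and always zero.
#' @param smiles Character vector of standardized SMILES.
#' @return Binary matrix with 167 columns.
#' @export
maccs <- function(smiles) feature_matrix(smiles, "maccs")

#' Continuous physicochemical descriptor block
#'
#' @param smiles Character vector of standardized SMILES.
#' @return Numeric matrix (~210 RDKit 2-D descriptors); non-finite values as
#'   `NA`.
#' @export
descriptor_block <- function(smiles) feature_matrix(smiles, "descriptors")

.new_selection <- function(indices, method, detail = NULL) {
  structure(list(indices = sort(unique(as.integer(indices))),
                 method = method, detail = detail),
            class = "ss_selection")
}

#' @export
print.ss_selection <- function(x, ...) {
  cat("Feature selection (", x$method, "): ", length(x$indices),
      " features retained\n", sep = "")
  invisible(x)
}

#' Drop descriptor columns that are non-finite for any training compound
#'
#' @param X Feature matrix (training fold).
#' @return An `ss_selection` with `method = "finite"`.
#' @export
drop_nonfinite <- function(X) {
  keep <- which(apply(X, 2, function(col) all(is.finite(col))))
  if (!length(keep)) stop("no informative features: all columns non-finite")
  .new_selection(keep, "finite")
}

#' Low-variance feature filter
#'
#' Retains exactly the features whose (population) variance across the
#' training fold exceeds `threshold`; for a binary bit with on-fraction p this
#' is p(1-p).
#'
#' @param X Feature matrix (training fold only).
#' @param threshold Variance threshold; default 0.01.
#' @return An `ss_selection` with `method = "variance"`.
#' @export
variance_filter <- function(X, threshold = 0.01) {
  stopifnot(is.matrix(X), nrow(X) >= 1)
  n <- nrow(X)
  v <- apply(X, 2, function(col) mean((col - mean(col))^2))
  keep <- which(v > threshold)
  if (!length(keep)) stop("no informative features: all variances <= ", threshold)
  .new_selection(keep, "variance", detail = list(threshold = threshold))
}

#' Recursive feature elimination
#'
#' Ranks features by impurity importance from a small random forest and
#' iteratively drops the lowest-importance 10% of the remaining features until
#' exactly `n_target` are left. Applied to continuous descriptor models;
#' fingerprint models keep raw bit identity for atom-level attribution.
#'
#' @param X Feature matrix (post variance filter, training fold).
#' @param y Labels (factor or integer classes).
#' @param n_target Number of features to retain.
#' @param seed Integer seed for the ranking forests.
#' @param step Fraction of remaining features eliminated per round (default
#'   0.1).
#' @param num_trees Trees per ranking forest (default 200).
#' @return An `ss_selection` with `method = "rfe"`.
#' @export
rfe_select <- function(X, y, n_target, seed = 1, step = 0.1, num_trees = 200) {
  stopifnot(is.matrix(X), nrow(X) == length(y), n_target >= 1)
  if (n_target > ncol(X)) {
    stop("n_target (", n_target, ") exceeds available features (", ncol(X), ")")
  }
  current <- seq_len(ncol(X))
  y <- factor(y)
  round_i <- 0L
  while (length(current) > n_target) {
    round_i <- round_i + 1L
    df <- as.data.frame(X[, current, drop = FALSE])
    names(df) <- paste0("f", current)
    rf <- ranger::ranger(x = df, y = y, num.trees = num_trees,
                         importance = "impurity",
                         seed = seed + round_i, num.threads = 1)
    imp <- rf$variable.importance
    n_drop <- min(max(1L, ceiling(step * length(current))),
                  length(current) - n_target)
    drop_local <- order(imp, decreasing = FALSE)[seq_len(n_drop)]
    current <- current[-drop_local]
  }
  .new_selection(current, "rfe", detail = list(n_target = n_target, seed = seed))
}

#' Apply a feature selection to a matrix
#'
#' @param selection An `ss_selection`.
#' @param X Feature matrix with the original (pre-selection) columns.
#' @return `X` restricted to the retained columns.
#' @export
apply_selection <- function(selection, X) {
  stopifnot(inherits(selection, "ss_selection"))
  if (max(selection$indices) > ncol(X)) stop("selection indices out of bounds")
  X[, selection$indices, drop = FALSE]
}

#' Fit a min-max scaler on a training fold
#'
#' Learns per-feature minima and maxima from the training rows only, so that
#' the training fold maps into \[0, 1\]. External rows may map outside that
#' range (no clipping). A feature constant on the training fold maps to 0
#' everywhere.
#'
#' @param X Training-fold feature matrix.
#' @return An `ss_scaler` holding `min` and `max` per feature.
#' @export
fit_minmax <- function(X) {
  stopifnot(is.matrix(X), nrow(X) >= 1)
  structure(list(min = apply(X, 2, min), max = apply(X, 2, max)),
            class = "ss_scaler")
}

#' Apply a fitted min-max scaler
#'
#' @param scaler An `ss_scaler` from [fit_minmax()].
#' @param X Feature matrix with the same columns the scaler was fitted on.
#' @return Scaled matrix; training-range values land in \[0, 1\].
#' @export
apply_minmax <- function(scaler, X) {
  stopifnot(inherits(scaler, "ss_scaler"))
  if (ncol(X) != length(scaler$min)) {
    stop("feature count mismatch: scaler has ", length(scaler$min),
         ", matrix has ", ncol(X))
  }
  rng <- scaler$max - scaler$min
  out <- sweep(X, 2, scaler$min, "-")
  nz <- rng > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, rng[nz], "/")
  out[, !nz] <- 0
  out
}

# Composed per-fold pipeline: featurize -> (finite) -> variance -> (rfe) ->
# (minmax, descriptors only). Fitted on the training fold only.
fit_feature_pipeline <- function(train_smiles, kind, y = NULL,
                                 variance_threshold = 0.01,
                                 rfe_target = NULL, seed = 1) {
  X <- feature_matrix(train_smiles, kind)
  sels <- list()
  if (kind == "descriptors") {
    fin <- drop_nonfinite(X)
    X <- apply_selection(fin, X)
    sels$finite <- fin
  }
  vf <- variance_filter(X, variance_threshold)
  X <- apply_selection(vf, X)
  sels$variance <- vf
  if (!is.null(rfe_target) && kind == "descriptors") {
    stopifnot(!is.null(y))
    rfe <- rfe_select(X, y, n_target = min(rfe_target, ncol(X)), seed = seed)
    X <- apply_selection(rfe, X)
    sels$rfe <- rfe
  }
  scaler <- NULL
  if (kind == "descriptors") {
    scaler <- fit_minmax(X)
    X <- apply_minmax(scaler, X)
  }
  structure(list(kind = kind, selections = sels, scaler = scaler,
                 train_matrix = X),
            class = "ss_feature_pipeline")
}

apply_feature_pipeline <- function(pipeline, smiles) {
  stopifnot(inherits(pipeline, "ss_feature_pipeline"))
  X <- feature_matrix(smiles, pipeline$kind)
  for (sel in pipeline$selections) X <- apply_selection(sel, X)
  if (!is.null(pipeline$scaler)) {
    X[!is.finite(X)] <- 0  # descriptor failures on external rows
    X <- apply_minmax(pipeline$scaler, X)
  }
  X
}
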