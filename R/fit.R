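# The main modeling surface: ss_fit() returns a classed model object holding
# the fitted predictor together with its feature pipeline, applicability
# domain and calibrated probability threshold; predict() scores raw SMILES
# end to end.

#' Fit a skin sensitization classifier
#'
#' Fits the full modeling pipeline on a curated dataset: featurization
#' (fingerprints or descriptors), low-variance filtering (plus recursive
#' feature elimination and min-max scaling for descriptors), applicability
#' domain, optional Bayesian hyperparameter search, classifier training, and
#' — for binary tasks — threshold-moving calibration of the probability
#' cutoff on out-of-fold predictions of the training set.
#'
#' @param dataset An `ss_dataset` from [curate_dataset()] (task `"binary"` or
#'   `"multiclass"`).
#' @param feature_kind `"ecfp4"`, `"maccs"` or `"descriptors"`.
#' @param algorithm `"random_forest"`, `"gradient_boosting"` or `"svm"`.
#' @param n_trials Hyperparameter search trials (1 = library defaults).
#' @param seed Integer seed governing folds, search and training.
#' @param Z Applicability-domain significance parameter (default 0.5).
#' @param calibrate Select the probability threshold by geometric-mean
#'   maximization (binary only); `FALSE` fixes PT = 0.5.
#' @param variance_threshold Low-variance filter threshold (default 0.01).
#' @param rfe_target Retained descriptor count for recursive feature
#'   elimination (descriptors only; `NULL` = half the post-filter features).
#' @param params Optional explicit hyperparameters (bypasses tuning).
#' @param pt Optional explicit probability threshold (e.g. from a
#'   cross-validation run); bypasses internal calibration.
#' @return An `ss_model` with `print`, `summary` and `predict` methods.
#' @seealso [ss_crossval()] for externally validated performance estimates.
#' @export
ss_fit <- function(dataset, feature_kind = "ecfp4",
                   algorithm = "random_forest", n_trials = 1, seed = 1,
                   Z = 0.5, calibrate = TRUE, variance_threshold = 0.01,
                   rfe_target = NULL, params = NULL, pt = NULL) {
  stopifnot(inherits(dataset, "ss_dataset"))
  if (dataset$task == "continuous") {
    stop("ss_fit models classification tasks; see rogi()/activity_grid() for ",
         "continuous landscape analysis")
  }
  y <- dataset$y
  if (feature_kind == "descriptors" && is.null(rfe_target)) {
    rfe_target <- NA  # resolved after the variance filter
  }
  pipeline <- fit_feature_pipeline(
    dataset$smiles, feature_kind, y = y,
    variance_threshold = variance_threshold,
    rfe_target = if (is.null(rfe_target) || is.na(rfe_target)) NULL
                 else rfe_target,
    seed = seed)
  if (feature_kind == "descriptors" && !is.null(rfe_target) &&
      is.na(rfe_target)) {
    # default: keep half the post-variance descriptors
    half <- max(1L, ncol(pipeline$train_matrix) %/% 2L)
    pipeline <- fit_feature_pipeline(
      dataset$smiles, feature_kind, y = y,
      variance_threshold = variance_threshold, rfe_target = half, seed = seed)
  }
  X <- pipeline$train_matrix
  ad <- fit_ad(X, Z = Z)
  if (is.null(params)) {
    params <- if (n_trials > 1) {
      tune_hyperparameters(X, y, algorithm, n_trials = n_trials,
                           seed = seed)$params
    } else {
      default_params(algorithm, n_features = ncol(X))
    }
  }
  predictor <- train_predictor(X, y, algorithm, params, seed = seed)
  scan <- NULL
  if (dataset$task == "binary" && is.null(pt)) {
    if (calibrate) {
      oof <- .oof_probs(X, y, algorithm, params, k = 5, seed = seed)
      scan <- select_threshold(y, oof)
      pt <- attr(scan, "pt")
    } else {
      pt <- 0.5
    }
  }
  structure(
    list(task = dataset$task, scheme = dataset$scheme,
         feature_kind = feature_kind, algorithm = algorithm, params = params,
         pipeline = pipeline, predictor = predictor, ad = ad, pt = pt,
         calibration = scan, seed = seed, Z = Z,
         train_smiles = dataset$smiles, y = y,
         classes = predictor$classes),
    class = "ss_model")
}

# out-of-fold positive-class probabilities with the (fixed) global feature
# space; used for threshold calibration of a standalone fit
.oof_probs <- function(X, y, algorithm, params, k = 5, seed = 1) {
  folds <- suppressWarnings(make_fold_plan(y, k = k, seed = seed))
  p <- rep(NA_real_, length(y))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2) next
    pred <- train_predictor(X[tr, , drop = FALSE], y[tr], algorithm, params,
                            seed = seed)
    p[!tr] <- predict_prob(pred, X[!tr, , drop = FALSE])[, "1"]
  }
  p[is.na(p)] <- 0.5
  p
}

#' @export
print.ss_model <- function(x, ...) {
  cat("Skin sensitization ", x$task, " model (", x$scheme, ")\n", sep = "")
  cat("  features: ", x$feature_kind, " (",
      ncol(x$pipeline$train_matrix), " after selection)\n", sep = "")
  cat("  algorithm:", x$algorithm, "\n")
  if (x$task == "binary") {
    cat("  probability threshold:", format(x$pt, digits = 3), "\n")
  }
  cat("  applicability domain: D_c =", format(x$ad$cutoff, digits = 4),
      "(Z =", paste0(x$Z, ")"), "\n")
  cat("  training compounds:", length(x$train_smiles), "\n")
  invisible(x)
}

#' @export
summary.ss_model <- function(object, ...) {
  print(object)
  cat("\nClass counts:\n")
  print(table(object$y))
  cat("\nHyperparameters:\n")
  for (nm in names(object$params)) {
    cat("  ", nm, "=", format(object$params[[nm]]), "\n")
  }
  if (!is.null(object$calibration)) {
    cat("\n")
    print(object$calibration)
  }
  invisible(object)
}

#' Predict skin sensitization for new structures
#'
#' Scores raw SMILES end to end: standardization, featurization through the
#' model's fitted pipeline, class probabilities, calibrated calls and
#' applicability-domain checks. Unparsable or rejected structures are
#' reported per row (status column) and never abort the batch.
#'
#' @param object An `ss_model`.
#' @param newdata Character vector of SMILES (raw; standardized internally),
#'   or an `ss_dataset`.
#' @param ... Unused.
#' @return Data.frame with one row per input: `smiles`, `std_smiles`,
#'   `status`, probability column(s), `call`, `ad_distance`, `in_ad`.
#' @export
predict.ss_model <- function(object, newdata, ...) {
  smiles <- if (inherits(newdata, "ss_dataset")) newdata$smiles
            else as.character(newdata)
  std <- standardize_structure(smiles)
  out <- data.frame(smiles = smiles, std_smiles = std$std_smiles,
                    status = ifelse(std$status == "ok", "ok",
                                    paste0("error:", std$reason)),
                    stringsAsFactors = FALSE)
  classes <- object$classes
  for (k in classes) out[[paste0("prob_", k)]] <- NA_real_
  out$call <- NA_integer_
  out$ad_distance <- NA_real_
  out$in_ad <- NA
  ok <- which(std$status == "ok")
  if (length(ok)) {
    X <- apply_feature_pipeline(object$pipeline, std$std_smiles[ok])
    P <- predict_prob(object$predictor, X)
    for (k in classes) out[[paste0("prob_", k)]][ok] <- P[, k]
    if (object$task == "binary") {
      out$call[ok] <- apply_threshold(P[, "1"], object$pt)
    } else {
      out$call[ok] <- as.integer(classes[max.col(P, ties.method = "first")])
    }
    adc <- ad_check(object$ad, X)
    out$ad_distance[ok] <- adc$distance
    out$in_ad[ok] <- adc$in_domain
  }
  out
}
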