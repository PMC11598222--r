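# Five-fold external cross-validation with fold-isolated featurization,
# selection, scaling, applicability domain and model fitting; pooled
# out-of-fold threshold calibration; Y-randomization.

#' Externally cross-validate the modeling pipeline
#'
#' Splits the dataset into k stratified folds. For each fold, the entire
#' pipeline — featurization, feature selection, scaling, applicability
#' domain, optional hyperparameter search and classifier training — is fitted
#' on the 80% training split only, and the held-out 20% is scored. Out-of-fold
#' probabilities are pooled; for binary tasks the probability threshold is
#' then selected on the pooled out-of-fold predictions by geometric-mean
#' maximization (one PT per model). Performance metrics are computed over
#' in-domain out-of-fold compounds, with coverage reporting the in-domain
#' fraction.
#'
#' @inheritParams ss_fit
#' @param k Number of folds (default 5).
#' @param undersample Randomly undersample the majority class before
#'   cross-validation (default TRUE for multiclass, FALSE for binary).
#' @return An `ss_cv`: out-of-fold prediction table (`oof`), selected `pt`,
#'   pooled metrics report (`pooled`, in-domain compounds), per-fold metric
#'   list (`per_fold`), `coverage` (percent in-domain) and the run `config`.
#' @export
ss_crossval <- function(dataset, feature_kind = "ecfp4",
                        algorithm = "random_forest", k = 5, n_trials = 1,
                        seed = 1, Z = 0.5, calibrate = TRUE,
                        variance_threshold = 0.01, rfe_target = NULL,
                        undersample = NULL) {
  stopifnot(inherits(dataset, "ss_dataset"))
  if (dataset$task == "continuous") stop("cross-validation is for classifiers")
  if (is.null(undersample)) undersample <- dataset$task == "multiclass"
  if (undersample && dataset$task == "multiclass") {
    dataset <- undersample_majority(dataset, seed = seed)
  }
  y <- dataset$y
  folds <- make_fold_plan(y, k = k, seed = seed)
  classes <- sort(unique(y))
  oof <- data.frame(smiles = dataset$smiles, y = y, fold = as.integer(folds),
                    stringsAsFactors = FALSE)
  for (kk in classes) oof[[paste0("prob_", kk)]] <- NA_real_
  oof$ad_distance <- NA_real_
  oof$in_ad <- NA
  skipped <- integer(0)
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2) {
      warning("fold ", f, " skipped: single class in training split")
      skipped <- c(skipped, f)
      next
    }
    pipe <- fit_feature_pipeline(dataset$smiles[tr], feature_kind, y = y[tr],
                                 variance_threshold = variance_threshold,
                                 rfe_target = rfe_target, seed = seed + f)
    X_tr <- pipe$train_matrix
    ad <- fit_ad(X_tr, Z = Z)
    params <- if (n_trials > 1) {
      tune_hyperparameters(X_tr, y[tr], algorithm, n_trials = n_trials,
                           seed = seed + f)$params
    } else {
      default_params(algorithm, n_features = ncol(X_tr))
    }
    pred <- train_predictor(X_tr, y[tr], algorithm, params, seed = seed + f)
    X_te <- apply_feature_pipeline(pipe, dataset$smiles[!tr])
    P <- predict_prob(pred, X_te)
    for (kk in classes) oof[[paste0("prob_", kk)]][!tr] <- P[, as.character(kk)]
    adc <- ad_check(ad, X_te)
    oof$ad_distance[!tr] <- adc$distance
    oof$in_ad[!tr] <- adc$in_domain
  }
  scored <- !is.na(oof$in_ad)
  oof_s <- oof[scored, , drop = FALSE]
  scan <- NULL
  if (dataset$task == "binary") {
    p1 <- oof_s$prob_1
    if (calibrate) {
      scan <- select_threshold(oof_s$y, p1)
      pt <- attr(scan, "pt")
    } else {
      pt <- 0.5
    }
    oof$call <- NA_integer_
    oof$call[scored] <- apply_threshold(p1, pt)
    pooled <- metrics_report(oof_s$y, apply_threshold(p1, pt), p1,
                             in_ad = oof_s$in_ad, task = "binary")
  } else {
    pt <- NA_real_
    Pm <- as.matrix(oof_s[, paste0("prob_", classes), drop = FALSE])
    colnames(Pm) <- as.character(classes)
    calls <- classes[max.col(Pm, ties.method = "first")]
    oof$call <- NA_integer_
    oof$call[scored] <- as.integer(calls)
    pooled <- metrics_report(oof_s$y, calls, Pm, in_ad = oof_s$in_ad,
                             task = "multiclass")
  }
  per_fold <- lapply(sort(setdiff(unique(folds), skipped)), function(f) {
    sel <- oof$fold == f & scored
    if (!sum(sel)) return(NULL)
    if (dataset$task == "binary") {
      metrics_report(oof$y[sel], oof$call[sel], oof$prob_1[sel],
                     in_ad = oof$in_ad[sel], task = "binary")
    } else {
      Pm <- as.matrix(oof[sel, paste0("prob_", classes), drop = FALSE])
      colnames(Pm) <- as.character(classes)
      metrics_report(oof$y[sel], oof$call[sel], Pm, in_ad = oof$in_ad[sel],
                     task = "multiclass")
    }
  })
  structure(
    list(oof = oof, pt = pt, calibration = scan, pooled = pooled,
         per_fold = per_fold,
         coverage = 100 * mean(oof$in_ad[scored]),
         dataset = dataset,
         config = list(task = dataset$task, scheme = dataset$scheme,
                       feature_kind = feature_kind, algorithm = algorithm,
                       k = k, n_trials = n_trials, seed = seed, Z = Z,
                       calibrate = calibrate,
                       variance_threshold = variance_threshold,
                       rfe_target = rfe_target, undersample = undersample)),
    class = "ss_cv")
}

#' @export
print.ss_cv <- function(x, ...) {
  cfg <- x$config
  cat(cfg$k, "-fold external cross-validation (", cfg$task, " ", cfg$scheme,
      ", ", cfg$feature_kind, " + ", cfg$algorithm, ")\n", sep = "")
  m <- x$pooled
  fmt <- function(v) ifelse(is.na(v), "undef", format(round(v, 3), nsmall = 2))
  cat("  pooled (in-domain): CCR=", fmt(m$CCR), " SE=", fmt(m$SE),
      " SP=", fmt(m$SP), " PPV=", fmt(m$PPV), " NPV=", fmt(m$NPV),
      " AUC=", fmt(m$AUC), "\n", sep = "")
  cat("  coverage: ", round(x$coverage, 1), "%", sep = "")
  if (cfg$task == "binary") cat("; PT = ", format(x$pt, digits = 3), sep = "")
  cat("\n")
  invisible(x)
}

#' @export
summary.ss_cv <- function(object, ...) {
  print(object)
  cat("\nPer-fold CCR:\n")
  ccrs <- vapply(object$per_fold, function(m) {
    if (is.null(m)) NA_real_ else m$CCR
  }, 0)
  print(round(ccrs, 3))
  invisible(object)
}

#' Y-randomization test
#'
#' Repeats the full cross-validation with labels shuffled independently each
#' round (derived seeds). A real model should clearly outperform the shuffled
#' models, whose CCR should center near chance; this guards against chance
#' correlation.
#'
#' @inheritParams ss_crossval
#' @param rounds Number of shuffling rounds (default 10).
#' @return An `ss_yrand`: list with `reports` (pooled metrics per round) and
#'   `ccr` (vector of shuffled CCRs).
#' @export
y_randomize <- function(dataset, feature_kind = "ecfp4",
                        algorithm = "random_forest", k = 5, n_trials = 1,
                        seed = 1, rounds = 10, ...) {
  stopifnot(rounds >= 1)
  reports <- vector("list", rounds)
  for (r in seq_len(rounds)) {
    shuffled <- dataset
    rseed <- seed + 7919L * r
    rng <- .restore_seed_state()
    set.seed(rseed)
    shuffled$y <- sample(dataset$y)
    rng()
    cv <- suppressWarnings(
      ss_crossval(shuffled, feature_kind = feature_kind,
                  algorithm = algorithm, k = k, n_trials = n_trials,
                  seed = rseed, ...))
    reports[[r]] <- cv$pooled
  }
  structure(list(reports = reports,
                 ccr = vapply(reports, function(m) m$CCR, 0)),
            class = "ss_yrand")
}

#' @export
print.ss_yrand <- function(x, ...) {
  cat("Y-randomization:", length(x$ccr), "rounds; shuffled CCR mean =",
      format(mean(x$ccr), digits = 3), ", max =",
      format(max(x$ccr), digits = 3), "\n")
  invisible(x)
}
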