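# Classifier training for the three algorithm families. Every predictor
# exposes class probabilities through predict_prob(); all fits are
# deterministic given the seed.

ALGORITHMS <- c("random_forest", "gradient_boosting", "svm")

.y_factor <- function(y) {
  classes <- sort(unique(as.character(y)))
  factor(as.character(y), levels = classes)
}

# Platt scaling: fit sigmoid P(y=1|f) = 1/(1+exp(A f + B)) on decision values
# with the standard smoothed targets; deterministic (BFGS on a convex loss).
.fit_platt <- function(f, y01) {
  n_pos <- sum(y01 == 1); n_neg <- sum(y01 == 0)
  t <- ifelse(y01 == 1, (n_pos + 1) / (n_pos + 2), 1 / (n_neg + 2))
  nll <- function(ab) {
    z <- ab[1] * f + ab[2]
    # numerically stable cross-entropy: -sum(t*log(p) + (1-t)*log(1-p))
    # with p = 1/(1+exp(z)): loss = sum(log(1+exp(z)) - (1-t)*z)
    sum(log1p(exp(-abs(z))) + pmax(z, 0) - (1 - t) * z)
  }
  fit <- stats::optim(c(A = -1, B = 0), nll, method = "BFGS")
  fit$par
}

.apply_platt <- function(par, f) 1 / (1 + exp(par[1] * f + par[2]))

# decision values oriented so that positive favors the second factor level
.svm_decision <- function(fit, X, levels2) {
  dv <- attr(predict(fit, X, decision.values = TRUE), "decision.values")
  cn <- colnames(dv)[1]
  d <- as.numeric(dv[, 1])
  if (identical(cn, paste(levels2[2], levels2[1], sep = "/"))) d else -d
}

.fit_svm_binary <- function(X, y01, cost, gamma, seed) {
  yf <- factor(y01, levels = c(0, 1))
  set.seed(seed)
  fit <- e1071::svm(x = X, y = yf, kernel = "radial", cost = cost,
                    gamma = gamma, scale = FALSE)
  f <- .svm_decision(fit, X, levels(yf))
  list(svm = fit, platt = .fit_platt(f, y01))
}

#' Train a classifier
#'
#' Fits one of the three supported algorithm families on a feature matrix:
#' `"random_forest"` (ranger probability forest), `"gradient_boosting"`
#' (xgboost with leaf-wise lossguide growth) or `"svm"` (RBF support vector
#' machine; probabilities via in-package Platt scaling, one-vs-rest for
#' multiclass). The fitted predictor emits class probabilities summing to 1
#' per row and is deterministic given `seed`.
#'
#' @param X Numeric feature matrix (rows = compounds).
#' @param y Class labels (two or more classes; a single-class `y` errors).
#' @param algorithm One of `"random_forest"`, `"gradient_boosting"`, `"svm"`.
#' @param params Hyperparameter list; missing entries take the documented
#'   defaults (see [default_params()]).
#' @param seed Integer seed.
#' @return An `ss_predictor`.
#' @export
train_predictor <- function(X, y, algorithm = ALGORITHMS, params = list(),
                            seed = 1) {
  algorithm <- match.arg(algorithm)
  stopifnot(is.matrix(X), nrow(X) == length(y))
  yf <- .y_factor(y)
  classes <- levels(yf)
  if (length(classes) < 2) stop("single-class y: cannot train a classifier")
  params <- modifyList(default_params(algorithm, n_features = ncol(X)), params)
  fit <- switch(
    algorithm,
    random_forest = {
      df <- as.data.frame(X)
      names(df) <- paste0("f", seq_len(ncol(X)))
      ranger::ranger(x = df, y = yf, probability = TRUE,
                     num.trees = params$num_trees,
                     max.depth = params$max_depth,
                     min.node.size = params$min_node_size,
                     seed = seed, num.threads = 1)
    },
    gradient_boosting = {
      if (length(classes) == 2) {
        obj <- list(objective = "binary:logistic")
        label <- as.integer(yf) - 1L
      } else {
        obj <- list(objective = "multi:softprob",
                    num_class = length(classes))
        label <- as.integer(yf) - 1L
      }
      dtrain <- xgboost::xgb.DMatrix(X, label = label, nthread = 1)
      xgboost::xgb.train(
        params = c(obj, list(eta = params$learning_rate,
                             max_leaves = params$max_leaves,
                             max_depth = 0,
                             grow_policy = "lossguide",
                             tree_method = "hist",
                             nthread = 1,
                             seed = seed)),
        data = dtrain, nrounds = params$n_estimators, verbose = 0)
    },
    svm = {
      if (length(classes) == 2) {
        .fit_svm_binary(X, as.integer(yf) - 1L, params$cost, params$gamma, seed)
      } else {
        # one-vs-rest with Platt scaling per class, normalized
        lapply(classes, function(k) {
          .fit_svm_binary(X, as.integer(yf == k), params$cost, params$gamma,
                          seed)
        })
      }
    }
  )
  structure(list(algorithm = algorithm, params = params, classes = classes,
                 n_features = ncol(X), seed = seed, fit = fit),
            class = "ss_predictor")
}

#' Class probabilities from a fitted predictor
#'
#' @param predictor An `ss_predictor` from [train_predictor()].
#' @param X Feature matrix in the predictor's feature space.
#' @return Matrix (rows x classes) of probabilities summing to 1 per row,
#'   with column names equal to the class labels.
#' @export
predict_prob <- function(predictor, X) {
  stopifnot(inherits(predictor, "ss_predictor"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != predictor$n_features) {
    stop("feature count mismatch: predictor expects ", predictor$n_features,
         ", got ", ncol(X))
  }
  classes <- predictor$classes
  P <- switch(
    predictor$algorithm,
    random_forest = {
      df <- as.data.frame(X)
      names(df) <- paste0("f", seq_len(ncol(X)))
      p <- predict(predictor$fit, data = df, num.threads = 1)$predictions
      p[, classes, drop = FALSE]
    },
    gradient_boosting = {
      p <- predict(predictor$fit, xgboost::xgb.DMatrix(X, nthread = 1))
      if (length(classes) == 2) {
        cbind(1 - p, p)
      } else {
        m <- if (is.matrix(p)) p else matrix(p, ncol = length(classes),
                                             byrow = TRUE)
        m / rowSums(m)  # absorb float32 rounding from the booster
      }
    },
    svm = {
      if (length(classes) == 2) {
        f <- .svm_decision(predictor$fit$svm, X, c("0", "1"))
        p1 <- .apply_platt(predictor$fit$platt, f)
        cbind(1 - p1, p1)
      } else {
        raw <- vapply(predictor$fit, function(m) {
          .apply_platt(m$platt, .svm_decision(m$svm, X, c("0", "1")))
        }, numeric(nrow(X)))
        if (is.null(dim(raw))) raw <- matrix(raw, nrow = 1)
        raw / rowSums(raw)
      }
    }
  )
  colnames(P) <- classes
  rownames(P) <- rownames(X)
  P
}

#' @export
print.ss_predictor <- function(x, ...) {
  cat("Fitted", x$algorithm, "classifier:", length(x$classes), "classes,",
      x$n_features, "features\n")
  invisible(x)
}
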