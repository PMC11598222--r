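# Bayesian hyperparameter search: Latin-hypercube initial design followed by
# a Gaussian-process surrogate with expected-improvement acquisition, run in
# the unit cube over each algorithm's documented search space. The objective
# is mean correct classification rate (CCR) over a stratified inner
# cross-validation of the training split; trial 0 always evaluates the
# library-default configuration, so the returned configuration is never worse
# than the default under the tuning objective.

# documented search spaces (log-scaled where ranges span decades)
.search_space <- function(algorithm, n_features) {
  switch(algorithm,
    random_forest = list(
      num_trees = list(type = "int", lo = 100, hi = 1000, log = FALSE),
      max_depth = list(type = "int", lo = 3, hi = 30, log = FALSE)
    ),
    gradient_boosting = list(
      max_leaves = list(type = "int", lo = 15, hi = 255, log = TRUE),
      learning_rate = list(type = "float", lo = 1e-3, hi = 0.3, log = TRUE),
      n_estimators = list(type = "int", lo = 100, hi = 1000, log = TRUE)
    ),
    svm = list(
      cost = list(type = "float", lo = 1e-2, hi = 1e3, log = TRUE),
      gamma = list(type = "float", lo = 1e-4, hi = 10, log = TRUE)
    ),
    stop("unknown algorithm: ", algorithm)
  )
}

#' Default hyperparameters per algorithm
#'
#' The library-default configurations (evaluated as trial 0 of every tuning
#' run): random forest with 500 trees, depth 30, node size 1 (respectively 5
#' for probability smoothing); gradient boosting with 31 leaves, learning
#' rate 0.1, 100 rounds; RBF SVM with cost 1 and gamma 1/n_features.
#'
#' @param algorithm Algorithm name.
#' @param n_features Feature count (sets the SVM gamma default).
#' @return Named list of hyperparameters.
#' @export
default_params <- function(algorithm = ALGORITHMS, n_features = NULL) {
  algorithm <- match.arg(algorithm)
  switch(algorithm,
    random_forest = list(num_trees = 500, max_depth = 30, min_node_size = 5),
    gradient_boosting = list(max_leaves = 31, learning_rate = 0.1,
                             n_estimators = 100),
    svm = list(cost = 1,
               gamma = if (is.null(n_features)) 0.01 else 1 / n_features)
  )
}

.to_unit <- function(params, space) {
  vapply(names(space), function(nm) {
    s <- space[[nm]]
    v <- params[[nm]]
    if (s$log) (log(v) - log(s$lo)) / (log(s$hi) - log(s$lo))
    else (v - s$lo) / (s$hi - s$lo)
  }, 0)
}

.from_unit <- function(u, space) {
  out <- list()
  for (i in seq_along(space)) {
    s <- space[[i]]
    v <- if (s$log) exp(log(s$lo) + u[i] * (log(s$hi) - log(s$lo)))
         else s$lo + u[i] * (s$hi - s$lo)
    if (s$type == "int") v <- as.integer(round(v))
    out[[names(space)[i]]] <- v
  }
  out
}

# GP posterior (RBF kernel, fixed lengthscale on the unit cube) and expected
# improvement of candidate points given observed (U, y).
.gp_ei <- function(U, y, cand, lengthscale = 0.3, nugget = 1e-6) {
  mu_y <- mean(y); sd_y <- sd(y)
  if (!is.finite(sd_y) || sd_y == 0) sd_y <- 1
  z <- (y - mu_y) / sd_y
  sq <- function(A, B) outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  K <- exp(-sq(U, U) / (2 * lengthscale^2)) + diag(nugget, nrow(U))
  Ks <- exp(-sq(cand, U) / (2 * lengthscale^2))
  alpha <- solve(K, z)
  mu <- as.numeric(Ks %*% alpha)
  v <- pmax(1 - rowSums((Ks %*% solve(K)) * Ks), nugget)
  sdv <- sqrt(v)
  best <- max(z)
  imp <- mu - best
  ei <- imp * pnorm(imp / sdv) + sdv * dnorm(imp / sdv)
  ei
}

# tuning objective: mean CCR over a stratified inner CV at the default
# decision rule (0.5 for binary, argmax for multiclass)
.inner_cv_ccr <- function(X, y, algorithm, params, inner_k, seed) {
  folds <- make_fold_plan(y, k = inner_k, seed = seed)
  ccrs <- c()
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2) next
    pred <- train_predictor(X[tr, , drop = FALSE], y[tr], algorithm,
                            params, seed = seed)
    P <- predict_prob(pred, X[!tr, , drop = FALSE])
    yt <- y[!tr]
    if (length(pred$classes) == 2) {
      call <- as.integer(P[, "1"] >= 0.5)
      m <- binary_metrics(confusion_counts(yt, call))
    } else {
      call <- as.integer(pred$classes[max.col(P, ties.method = "first")])
      m <- multiclass_metrics(yt, call,
                              classes = as.integer(pred$classes))
    }
    if (is.finite(m$CCR)) ccrs <- c(ccrs, m$CCR)
  }
  if (!length(ccrs)) return(NA_real_)
  mean(ccrs)
}

#' Bayesian hyperparameter search
#'
#' Maximizes mean inner-cross-validation CCR over the documented search space
#' for the given algorithm. Trial 0 evaluates the library-default
#' configuration; the next few trials come from a seeded Latin-hypercube
#' design; remaining trials are proposed by a Gaussian-process surrogate with
#' expected-improvement acquisition. With `n_trials = 1` the default
#' configuration is returned. The whole trace is reproducible from `seed`.
#'
#' @param X Training feature matrix.
#' @param y Training labels.
#' @param algorithm One of `"random_forest"`, `"gradient_boosting"`, `"svm"`.
#' @param n_trials Total number of evaluated configurations (>= 1).
#' @param seed Integer seed.
#' @param inner_k Inner CV folds for the objective (default 3).
#' @return List with `params` (the best configuration), `objective` (its
#'   inner-CV CCR) and `trace` (data.frame of all trials).
#' @export
tune_hyperparameters <- function(X, y, algorithm = ALGORITHMS, n_trials = 10,
                                 seed = 1, inner_k = 3) {
  algorithm <- match.arg(algorithm)
  stopifnot(n_trials >= 1)
  space <- .search_space(algorithm, ncol(X))
  d <- length(space)
  defaults <- default_params(algorithm, n_features = ncol(X))
  # clamp defaults into the space for the unit-cube representation
  cand_list <- list(defaults)
  n_init <- min(n_trials - 1, 2 * d)
  if (n_init > 0) {
    rng <- .restore_seed_state(); on.exit(rng())
    set.seed(seed)
    L <- lhs::randomLHS(n_init, d)
    for (i in seq_len(n_init)) cand_list[[i + 1]] <- .from_unit(L[i, ], space)
  }
  evals <- data.frame()
  U <- matrix(numeric(0), ncol = d)
  scores <- c()
  eval_trial <- function(params, i) {
    obj <- suppressWarnings(
      .inner_cv_ccr(X, y, algorithm, params, inner_k, seed = seed + 1000L))
    if (is.na(obj)) obj <- 0
    obj
  }
  for (i in seq_along(cand_list)) {
    if (length(scores) >= n_trials) break
    obj <- eval_trial(cand_list[[i]], i)
    tun <- names(space)
    u <- .to_unit(cand_list[[i]][tun], space)
    u <- pmin(pmax(u, 0), 1)
    U <- rbind(U, u)
    scores <- c(scores, obj)
  }
  while (length(scores) < n_trials) {
    set.seed(seed + 7L * length(scores))
    cand <- matrix(runif(200 * d), ncol = d)
    ei <- .gp_ei(U, scores, cand)
    nxt <- .from_unit(cand[which.max(ei), ], space)
    cand_list[[length(scores) + 1]] <- nxt
    obj <- eval_trial(nxt, length(scores) + 1)
    U <- rbind(U, .to_unit(nxt[names(space)], space))
    scores <- c(scores, obj)
  }
  trace <- data.frame(trial = seq_along(scores) - 1L, objective = scores)
  best <- which.max(scores)
  best_params <- modifyList(defaults, cand_list[[best]])
  list(params = best_params, objective = scores[best], trace = trace)
}
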