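# Classification performance metrics: confusion counts, SE/SP/CCR/PPV/NPV,
# macro one-vs-rest multiclass metrics, and rank-based AUC.

#' Confusion counts for one positive class
#'
#' @param y_true True labels.
#' @param y_called Predicted labels (same length).
#' @param positive_class The label counted as positive (default 1).
#' @param binary If TRUE (default), labels outside \{0, 1\} are an error.
#' @return Named integer vector `c(TP, TN, FP, FN)`.
#' @export
confusion_counts <- function(y_true, y_called, positive_class = 1,
                             binary = TRUE) {
  if (length(y_true) != length(y_called)) stop("length mismatch")
  if (binary && !all(c(y_true, y_called) %in% c(0, 1))) {
    stop("binary labels must be in {0, 1}")
  }
  pos_t <- y_true == positive_class
  pos_c <- y_called == positive_class
  c(TP = sum(pos_t & pos_c), TN = sum(!pos_t & !pos_c),
    FP = sum(!pos_t & pos_c), FN = sum(pos_t & !pos_c))
}

.safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Binary classification metrics from confusion counts
#'
#' Sensitivity SE = TP/(TP+FN), specificity SP = TN/(TN+FP), correct
#' classification rate CCR = (SE+SP)/2 (balanced accuracy), positive
#' predictive value PPV = TP/(TP+FP) and negative predictive value
#' NPV = TN/(TN+FN). A metric with a zero denominator is undefined and
#' reported as `NA` (never silently 0).
#'
#' @param counts Named vector from [confusion_counts()].
#' @return List with elements `SE`, `SP`, `CCR`, `PPV`, `NPV`.
#' @export
binary_metrics <- function(counts) {
  stopifnot(all(c("TP", "TN", "FP", "FN") %in% names(counts)))
  tp <- counts[["TP"]]; tn <- counts[["TN"]]
  fp <- counts[["FP"]]; fn <- counts[["FN"]]
  se <- .safe_ratio(tp, tp + fn)
  sp <- .safe_ratio(tn, tn + fp)
  list(SE = se, SP = sp, CCR = (se + sp) / 2,
       PPV = .safe_ratio(tp, tp + fp), NPV = .safe_ratio(tn, tn + fn))
}

#' Macro one-vs-rest multiclass metrics
#'
#' Computes SE/SP/PPV/NPV for each class against the rest and macro-averages
#' with equal class weights; classes where a metric is undefined are excluded
#' from that metric's average. The macro CCR is (macro SE + macro SP)/2.
#'
#' @param y_true True class labels (subset of `classes`).
#' @param y_called Predicted class labels.
#' @param classes Class universe (default `0:2`).
#' @return List with macro `SE`, `SP`, `CCR`, `PPV`, `NPV` and a `per_class`
#'   list of per-class metric lists.
#' @export
multiclass_metrics <- function(y_true, y_called, classes = 0:2) {
  if (length(y_true) != length(y_called)) stop("length mismatch")
  if (!all(y_true %in% classes)) stop("labels outside the class universe")
  per_class <- lapply(classes, function(k) {
    binary_metrics(confusion_counts(as.integer(y_true == k),
                                    as.integer(y_called == k)))
  })
  names(per_class) <- paste0("class_", classes)
  macro <- function(metric) {
    vals <- vapply(per_class, function(m) m[[metric]], 0)
    if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  }
  se <- macro("SE"); sp <- macro("SP")
  list(SE = se, SP = sp, CCR = (se + sp) / 2,
       PPV = macro("PPV"), NPV = macro("NPV"), per_class = per_class)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a random positive is
#' ranked above a random negative, counting ties as one half. For a
#' probability matrix (multiclass), returns the macro average of one-vs-rest
#' AUCs over classes present in `y_true`.
#'
#' @param y_true Binary labels (0/1), or class labels with a matrix `p`.
#' @param p Predicted probabilities for the positive class (vector), or an
#'   n x classes probability matrix with column names equal to the classes.
#' @return AUC in \[0, 1\]; `NA` if only one class is present.
#' @export
auc_score <- function(y_true, p) {
  if (is.matrix(p)) {
    classes <- colnames(p)
    if (is.null(classes)) classes <- as.character(seq_len(ncol(p)) - 1L)
    aucs <- vapply(seq_along(classes), function(j) {
      yk <- as.integer(as.character(y_true) == classes[j])
      auc_score(yk, p[, j])
    }, 0)
    if (all(is.na(aucs))) return(NA_real_)
    return(mean(aucs, na.rm = TRUE))
  }
  if (length(y_true) != length(p)) stop("length mismatch")
  n1 <- sum(y_true == 1); n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(p, ties.method = "average")
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Pooled metrics report for a set of scored compounds
#'
#' Convenience wrapper combining confusion-based metrics, AUC and coverage
#' into one report, restricted to in-domain compounds when an `in_ad` flag is
#' supplied (out-of-domain compounds count against coverage only).
#'
#' @param y_true Labels.
#' @param y_called Calls.
#' @param p Probabilities (vector for binary, matrix for multiclass).
#' @param in_ad Logical in-domain flags (default all TRUE).
#' @param task `"binary"` or `"multiclass"`.
#' @return List of metrics plus `AUC`, `coverage` (percent) and `n_scored`.
#' @export
metrics_report <- function(y_true, y_called, p = NULL, in_ad = NULL,
                           task = c("binary", "multiclass")) {
  task <- match.arg(task)
  if (is.null(in_ad)) in_ad <- rep(TRUE, length(y_true))
  cov <- 100 * sum(in_ad) / length(y_true)
  yt <- y_true[in_ad]; yc <- y_called[in_ad]
  rep <- if (task == "binary") binary_metrics(confusion_counts(yt, yc))
         else multiclass_metrics(yt, yc)
  rep$AUC <- if (is.null(p)) NA_real_ else {
    pp <- if (is.matrix(p)) p[in_ad, , drop = FALSE] else p[in_ad]
    auc_score(yt, pp)
  }
  rep$coverage <- cov
  rep$n_scored <- sum(in_ad)
  rep
}
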