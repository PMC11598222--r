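# Threshold-moving calibration: choose the probability cutoff that maximizes
# the geometric mean of sensitivity and specificity on held-out predictions.

#' Geometric mean of sensitivity and specificity
#'
#' @param se Sensitivity in \[0, 1\].
#' @param sp Specificity in \[0, 1\].
#' @return sqrt(se * sp).
#' @export
gmean <- function(se, sp) {
  stopifnot(se >= 0, se <= 1, sp >= 0, sp <= 1)
  sqrt(se * sp)
}

#' Select a probability threshold by geometric-mean maximization
#'
#' Evaluates every candidate threshold (the observed unique probabilities plus
#' 0.5 — the geometric mean is piecewise constant between observed values, so
#' this scan is exact), calling positive iff p >= t, and returns the candidate
#' with the highest geometric mean of SE and SP. Ties are broken toward the
#' smallest threshold, which favors sensitivity.
#'
#' @param y_true Binary labels (both classes must be present).
#' @param p Predicted positive-class probabilities.
#' @return An `ss_threshold_scan`: data.frame of candidates with `threshold`,
#'   `SE`, `SP`, `gmean`, plus attributes `pt` (selected threshold) and
#'   `best_gmean`.
#' @export
select_threshold <- function(y_true, p) {
  if (length(y_true) != length(p)) stop("length mismatch")
  if (length(unique(y_true)) < 2) {
    stop("threshold selection needs both classes present")
  }
  cand <- sort(unique(c(p, 0.5)))
  n_pos <- sum(y_true == 1)
  n_neg <- sum(y_true == 0)
  scan <- vapply(cand, function(t) {
    call <- as.integer(p >= t)
    se <- sum(call == 1 & y_true == 1) / n_pos
    sp <- sum(call == 0 & y_true == 0) / n_neg
    c(se, sp, sqrt(se * sp))
  }, numeric(3))
  df <- data.frame(threshold = cand, SE = scan[1, ], SP = scan[2, ],
                   gmean = scan[3, ])
  best <- which.max(df$gmean)  # which.max returns the first (smallest) maximizer
  structure(df, class = c("ss_threshold_scan", "data.frame"),
            pt = df$threshold[best], best_gmean = df$gmean[best])
}

#' @export
print.ss_threshold_scan <- function(x, ...) {
  cat("Threshold scan over", nrow(x), "candidates; selected PT =",
      format(attr(x, "pt"), digits = 4),
      "(gmean =", format(attr(x, "best_gmean"), digits = 4), ")\n")
  invisible(x)
}

#' Apply a probability threshold
#'
#' Calls positive (1) iff p >= pt; the boundary is inclusive, so lowering the
#' threshold never turns a positive call negative.
#'
#' @param p Probabilities.
#' @param pt Threshold in (0, 1].
#' @return Integer vector of 0/1 calls.
#' @export
apply_threshold <- function(p, pt) {
  stopifnot(pt > 0, pt <= 1)
  as.integer(p >= pt)
}
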