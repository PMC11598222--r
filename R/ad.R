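# Euclidean nearest-neighbor applicability domain. A query compound is
# in-domain when the distance to its nearest training compound does not
# exceed D_c = mean + Z * sd of the within-training nearest-neighbor
# distances (Z = 0.5 by default).

#' Fit a nearest-neighbor applicability domain
#'
#' Computes, for each training compound, the Euclidean distance to its
#' nearest other training compound (1-NN by default; `k` averages over the k
#' nearest), then sets the domain cutoff to `D_c = mean + Z * sd` of those
#' distances. The feature matrix must be the same post-selection (and, for
#' descriptors, post-scaling) space the model consumes.
#'
#' @param X Training feature matrix (>= 2 rows).
#' @param Z Significance parameter controlling the cutoff (default 0.5).
#' @param k Number of training neighbors averaged per compound (default 1).
#' @return An `ss_ad` with the reference matrix, `d_bar`, `s`, `Z`, `cutoff`.
#' @export
fit_ad <- function(X, Z = 0.5, k = 1) {
  stopifnot(is.matrix(X))
  if (nrow(X) < 2) stop("applicability domain needs at least 2 training rows")
  D <- as.matrix(dist(X))
  diag(D) <- Inf
  nn <- apply(D, 1, function(row) mean(sort(row)[seq_len(min(k, length(row)))]))
  d_bar <- mean(nn)
  s <- if (length(nn) > 1) sd(nn) else 0
  structure(list(reference = X, d_bar = d_bar, s = s, Z = Z, k = k,
                 cutoff = d_bar + Z * s),
            class = "ss_ad")
}

#' @export
print.ss_ad <- function(x, ...) {
  cat("Applicability domain:", nrow(x$reference), "reference compounds;",
      "D_c =", format(x$cutoff, digits = 4),
      "(d_bar =", format(x$d_bar, digits = 4),
      ", s =", format(x$s, digits = 4), ", Z =", x$Z, ")\n")
  invisible(x)
}

#' Check compounds against an applicability domain
#'
#' @param state An `ss_ad` from [fit_ad()].
#' @param X Feature row(s): vector (one compound) or matrix.
#' @return Data.frame with `distance` (Euclidean distance to the nearest
#'   reference compound) and `in_domain` (distance <= cutoff).
#' @export
ad_check <- function(state, X) {
  stopifnot(inherits(state, "ss_ad"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != ncol(state$reference)) {
    stop("feature dimensionality mismatch: reference has ",
         ncol(state$reference), ", query has ", ncol(X))
  }
  ref <- state$reference
  # ||x - r||^2 = ||x||^2 + ||r||^2 - 2 x.r, minimized over reference rows
  cross <- X %*% t(ref)
  d2 <- outer(rowSums(X^2), rowSums(ref^2), "+") - 2 * cross
  d <- sqrt(pmax(apply(d2, 1, min), 0))
  data.frame(distance = as.numeric(d), in_domain = as.numeric(d) <= state$cutoff)
}

#' Applicability-domain coverage of a compound set
#'
#' @param state An `ss_ad`.
#' @param X Feature matrix of query compounds.
#' @return Percentage (0-100) of compounds inside the domain.
#' @export
ad_coverage <- function(state, X) {
  stopifnot(nrow(X) >= 1)
  100 * mean(ad_check(state, X)$in_domain)
}
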