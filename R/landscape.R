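# Activity-landscape analysis: normalized pairwise distances, roughness
# index (ROGI), 2-D MDS projection with interpolated activity grids, and
# chemical-space grouping on a seeded nonlinear embedding.

#' Normalized pairwise Euclidean distance matrix
#'
#' All-pairs Euclidean distances over a (min-max normalized) feature matrix,
#' rescaled into \[0, 1\] by the maximum distance.
#'
#' @param X Feature matrix (>= 2 rows; min-max normalize descriptors first).
#' @return Symmetric matrix with zero diagonal and maximum entry 1 (unless
#'   all rows coincide).
#' @export
normalized_distances <- function(X) {
  stopifnot(is.matrix(X))
  if (nrow(X) < 2) stop("need at least 2 rows for a distance matrix")
  D <- as.matrix(dist(X))
  m <- max(D)
  if (m > 0) D <- D / m
  D
}

#' Roughness index (ROGI) of an activity landscape
#'
#' Quantifies how quickly property dispersion is lost when the dataset is
#' coarse-grained by progressive distance-threshold clustering. The activity
#' is min-max normalized to \[0, 1\]; for every threshold t (all
#' complete-linkage merge heights plus 0 and 1), compounds are clustered at
#' distance t and replaced by size-weighted cluster means, and the weighted
#' standard deviation sigma(t) of the coarse-grained values is recorded.
#' ROGI = 2 * integral of (sigma(0) - sigma(t)) dt over \[0, 1\], by
#' trapezoidal integration. A constant activity gives exactly 0; the score is
#' invariant to positive affine transformations of the activity; rough
#' landscapes (activity cliffs) score higher.
#'
#' @param D Normalized distance matrix from [normalized_distances()].
#' @param activity Numeric activity vector (e.g. log10 doses or classes).
#' @return List with `rogi` (score), `thresholds`, `sigma` (dispersion per
#'   threshold) of class `ss_rogi`.
#' @export
rogi <- function(D, activity) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D), nrow(D) == length(activity))
  if (!all(is.finite(activity))) stop("activity must be finite")
  n <- length(activity)
  rng <- max(activity) - min(activity)
  a <- if (rng > 0) (activity - min(activity)) / rng else rep(0, n)
  wsd <- function(vals, sizes) {
    w <- sizes / sum(sizes)
    mu <- sum(w * vals)
    sqrt(sum(w * (vals - mu)^2))
  }
  sigma0 <- wsd(a, rep(1, n))
  off <- D[upper.tri(D)]
  if (length(unique(round(off, 12))) == 1L) {
    if (sigma0 > 0) {
      warning("all pairwise distances equal: activity landscape is maximally ",
              "rough; returning 2 * sigma(0)")
    }
    return(structure(list(rogi = 2 * sigma0, thresholds = c(0, 1),
                          sigma = c(sigma0, 0)), class = "ss_rogi"))
  }
  hc <- hclust(as.dist(D), method = "complete")
  heights <- pmin(pmax(hc$height, 0), 1)
  ts <- sort(unique(c(0, heights, 1)))
  sig <- vapply(ts, function(t) {
    cl <- cutree(hc, h = t)
    means <- tapply(a, cl, mean)
    sizes <- tapply(a, cl, length)
    wsd(as.numeric(means), as.numeric(sizes))
  }, 0)
  integrand <- sigma0 - sig
  score <- 2 * sum(diff(ts) * (head(integrand, -1) + integrand[-1]) / 2)
  structure(list(rogi = score, thresholds = ts, sigma = sig),
            class = "ss_rogi")
}

#' @export
print.ss_rogi <- function(x, ...) {
  cat("ROGI =", format(x$rogi, digits = 4), "over",
      length(x$thresholds), "thresholds\n")
  invisible(x)
}

#' 2-D metric multidimensional scaling
#'
#' Classical (metric) MDS of a distance matrix onto two dimensions. The
#' solution is deterministic; `seed` is accepted and recorded for interface
#' symmetry with the nonlinear embeddings.
#'
#' @param D Distance matrix.
#' @param seed Integer seed (recorded; the classical solution needs none).
#' @return n x 2 coordinate matrix (columns `z1`, `z2`).
#' @export
mds_embed <- function(D, seed = 1) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  k <- min(2L, nrow(D) - 1L)
  coords <- cmdscale(as.dist(D), k = k)
  if (ncol(coords) < 2) coords <- cbind(coords, 0)
  colnames(coords) <- c("z1", "z2")
  attr(coords, "seed") <- seed
  coords
}

#' Interpolated activity grid over 2-D coordinates
#'
#' Builds a regular `resolution x resolution` grid over the bounding box of
#' the projected coordinates and interpolates the activity by inverse
#' distance weighting (power 2). The interpolant passes exactly through the
#' data points and every grid value is a convex combination of the observed
#' activities, so it stays within their range.
#'
#' @param coords n x 2 coordinate matrix (e.g. from [mds_embed()]).
#' @param activity Activity values, one per row of `coords`.
#' @param resolution Grid resolution per axis (default 50).
#' @return List with `x`, `y` (grid axes) and `z` (resolution x resolution
#'   matrix of interpolated values), class `ss_grid`.
#' @export
activity_grid <- function(coords, activity, resolution = 50) {
  stopifnot(nrow(coords) == length(activity), resolution >= 2)
  if (nrow(coords) < 3) stop("need at least 3 points")
  centered <- sweep(as.matrix(coords[, 1:2]), 2, colMeans(coords[, 1:2]))
  if (qr(centered)$rank < 2) stop("points are collinear: cannot interpolate a surface")
  gx <- seq(min(coords[, 1]), max(coords[, 1]), length.out = resolution)
  gy <- seq(min(coords[, 2]), max(coords[, 2]), length.out = resolution)
  z <- matrix(NA_real_, resolution, resolution)
  for (i in seq_len(resolution)) {
    dx2 <- (gx[i] - coords[, 1])^2
    for (j in seq_len(resolution)) {
      d2 <- dx2 + (gy[j] - coords[, 2])^2
      hit <- which(d2 < 1e-12)
      if (length(hit)) {
        z[i, j] <- mean(activity[hit])
      } else {
        w <- 1 / d2
        z[i, j] <- sum(w * activity) / sum(w)
      }
    }
  }
  structure(list(x = gx, y = gy, z = z), class = "ss_grid")
}

#' Interpolate activity at arbitrary coordinates
#'
#' Same inverse-distance interpolant as [activity_grid()], evaluated at given
#' points; at a data coordinate it returns that datum.
#'
#' @inheritParams activity_grid
#' @param at m x 2 matrix of query coordinates.
#' @return Numeric vector of interpolated values.
#' @export
interpolate_activity <- function(coords, activity, at) {
  if (is.null(dim(at))) at <- matrix(at, ncol = 2)
  apply(at, 1, function(q) {
    d2 <- (q[1] - coords[, 1])^2 + (q[2] - coords[, 2])^2
    hit <- which(d2 < 1e-12)
    if (length(hit)) return(mean(activity[hit]))
    w <- 1 / d2
    sum(w * activity) / sum(w)
  })
}

# minimal DBSCAN on 2-D embeddings (Euclidean); noise points get group 0
.dbscan2d <- function(X, eps, min_pts) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  neighbors <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(neighbors, length, 0L) >= min_pts
  labels <- rep(0L, n)
  cluster <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cluster <- cluster + 1L
    labels[i] <- cluster
    frontier <- setdiff(neighbors[[i]], i)
    while (length(frontier)) {
      j <- frontier[1]
      frontier <- frontier[-1]
      if (labels[j] == 0L) {
        labels[j] <- cluster
        if (core[j]) frontier <- union(frontier, setdiff(neighbors[[j]],
                                                         which(labels != 0L)))
      }
    }
  }
  labels
}

#' Chemical-space grouping by seeded nonlinear embedding
#'
#' Computes radius-2 2048-bit Morgan fingerprints, removes low-variance bits,
#' embeds the compounds in two dimensions with a seeded UMAP (Jaccard metric)
#' and groups them by density-based clustering on the embedding (DBSCAN,
#' minimum group size `min_pts`, radius from a k-distance heuristic unless
#' given). Compounds are embedded in canonical-structure sort order, so the
#' partition is invariant to input ordering; a noise group (label 0) is
#' allowed.
#'
#' @param smiles Character vector of standardized SMILES (>= 10).
#' @param seed Integer seed for the embedding.
#' @param min_pts Minimum group size (default 3).
#' @param eps DBSCAN radius; default: 90th percentile of `min_pts`-nearest
#'   neighbor distances on the embedding.
#' @param n_neighbors UMAP neighborhood size (default 15).
#' @return An `ss_chemspace`: data.frame with `smiles`, `z1`, `z2`, `group`,
#'   plus attribute `seed`.
#' @export
chemspace_grouping <- function(smiles, seed = 1, min_pts = 3, eps = NULL,
                               n_neighbors = 15) {
  smiles <- as.character(smiles)
  if (length(smiles) < 10) stop("too few for embedding: need >= 10 compounds")
  uniq <- sort(unique(smiles))
  X <- feature_matrix(uniq, "morgan2")
  keep <- tryCatch(variance_filter(X, 0.01)$indices,
                   error = function(e) seq_len(ncol(X)))
  Xf <- X[, keep, drop = FALSE]
  onbits <- lapply(seq_len(nrow(Xf)), function(i) {
    as.list(unname(which(Xf[i, ] > 0)) - 1L)
  })
  emb <- chem_backend("embed", list(
    n = nrow(Xf), ncol = ncol(Xf), onbits = onbits,
    n_neighbors = n_neighbors, min_dist = 0.1, metric = "jaccard",
    seed = seed))
  coords <- do.call(rbind, lapply(emb$coords, unlist))
  if (is.null(eps)) {
    D <- as.matrix(dist(coords))
    kd <- apply(D, 1, function(r) sort(r)[min(min_pts + 1, length(r))])
    eps <- as.numeric(quantile(kd, 0.9))
  }
  groups <- .dbscan2d(coords, eps = eps, min_pts = min_pts)
  idx <- match(smiles, uniq)
  out <- data.frame(smiles = smiles, z1 = coords[idx, 1], z2 = coords[idx, 2],
                    group = groups[idx], stringsAsFactors = FALSE)
  structure(out, class = c("ss_chemspace", "data.frame"), seed = seed,
            eps = eps)
}
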