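# Stratified fold assignment and majority-class undersampling.

#' Build a stratified k-fold plan
#'
#' Partitions indices into k folds of near-equal size (differing by at most
#' one) while approximately preserving class proportions: within each class,
#' shuffled members are dealt cyclically across folds, and classes are laid
#' out consecutively so overall fold sizes stay balanced. A class with fewer
#' than k members triggers a warning and is spread as evenly as possible.
#'
#' @param labels Class labels, one per compound.
#' @param k Number of folds (default 5).
#' @param seed Integer seed; the same seed reproduces the same plan.
#' @return Integer vector of fold ids (1..k), one per compound, with
#'   attributes `k` and `seed`.
#' @export
make_fold_plan <- function(labels, k = 5, seed = 1) {
  n <- length(labels)
  stopifnot(k >= 2, n >= k)
  rng <- .restore_seed_state()
  on.exit(rng())
  set.seed(seed)
  tab <- table(labels)
  if (any(tab < k)) {
    warning("class(es) with fewer than k members: ",
            paste(names(tab)[tab < k], collapse = ", "),
            "; spreading as evenly as possible")
  }
  ord <- unlist(lapply(split(seq_len(n), labels), sample), use.names = FALSE)
  folds <- integer(n)
  folds[ord] <- ((seq_len(n) - 1L) %% k) + 1L
  structure(folds, k = k, seed = seed)
}

# save+restore the global RNG state so seeded helpers do not perturb callers
.restore_seed_state <- function() {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  function() {
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }
}

#' Randomly undersample the majority class of a multiclass dataset
#'
#' Reduces the largest class to the size of the second-largest class by
#' seeded random removal; all other classes are untouched. An already
#' balanced dataset is returned unchanged.
#'
#' @param dataset An `ss_dataset` of task `"multiclass"` (or any dataset with
#'   at least two classes).
#' @param seed Integer seed.
#' @return The dataset with the majority class reduced; removed compounds are
#'   appended to the drop log with action `"undersampled"`.
#' @export
undersample_majority <- function(dataset, seed = 1) {
  stopifnot(inherits(dataset, "ss_dataset"))
  tab <- sort(table(dataset$y), decreasing = TRUE)
  if (length(tab) < 2) stop("undersampling needs at least two classes")
  if (tab[1] == tab[2]) return(dataset)
  majority <- names(tab)[1]
  target <- as.integer(tab[2])
  idx_maj <- which(as.character(dataset$y) == majority)
  rng <- .restore_seed_state()
  on.exit(rng())
  set.seed(seed)
  drop <- sample(idx_maj, length(idx_maj) - target)
  dataset$log <- rbind(dataset$log,
                       .log_rows(dataset$smiles[drop], "undersampled",
                                 "majority_class"))
  dataset$smiles <- dataset$smiles[-drop]
  dataset$y <- dataset$y[-drop]
  dataset
}
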