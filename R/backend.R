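# Bridge to the bundled Python RDKit backend. All chemistry goes through
# chem_backend(); results are memoised per molecule so repeated featurization
# of the same structures costs one subprocess call in total.

.chem_cache <- new.env(parent = emptyenv())

backend_script <- function() {
  p <- system.file("python", "chem_backend.py", package = "skinsens")
  if (!nzchar(p)) stop("chem_backend.py not found in installed package")
  p
}

python_binary <- function() {
  Sys.getenv("SKINSENS_PYTHON", unset = "python")
}

#' Low-level call into the chemistry backend
#'
#' Serializes `payload` to JSON, runs the bundled RDKit helper, and parses the
#' JSON result. Not normally called directly; the featurization and curation
#' functions wrap it with caching.
#'
#' @param op Backend operation name (e.g. `"standardize"`, `"fingerprints"`).
#' @param payload Named list, JSON-serializable.
#' @return Parsed JSON result (lists, unsimplified).
#' @keywords internal
chem_backend <- function(op, payload) {
  inf <- tempfile(fileext = ".json")
  outf <- tempfile(fileext = ".json")
  on.exit(unlink(c(inf, outf)), add = TRUE)
  jsonlite::write_json(payload, inf, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  err <- tempfile(fileext = ".txt")
  on.exit(unlink(err), add = TRUE)
  status <- suppressWarnings(system2(python_binary(),
                                     c(backend_script(), op, inf, outf),
                                     stdout = FALSE, stderr = err))
  if (!identical(status, 0L)) {
    msg <- tryCatch(paste(readLines(err, warn = FALSE), collapse = "\n"),
                    error = function(e) "")
    stop("chemistry backend failed (op=", op, "): ", msg)
  }
  jsonlite::fromJSON(outf, simplifyVector = FALSE)
}

.cache_key <- function(...) paste(..., sep = "\r")

.cache_get <- function(keys) {
  lapply(keys, function(k) {
    if (exists(k, envir = .chem_cache, inherits = FALSE)) {
      get(k, envir = .chem_cache, inherits = FALSE)
    } else NULL
  })
}

.cache_put <- function(keys, values) {
  for (i in seq_along(keys)) assign(keys[[i]], values[[i]], envir = .chem_cache)
}

# Run `op` for the subset of smiles not yet cached, merge with cache.
# `extra` must be part of the cache key when it changes the result.
.cached_backend <- function(op, smiles, extra_key = "", payload_extra = list()) {
  keys <- vapply(smiles, function(s) .cache_key(op, extra_key, s), "")
  hits <- .cache_get(keys)
  miss <- which(vapply(hits, is.null, TRUE))
  if (length(miss)) {
    payload <- c(list(smiles = as.list(smiles[miss])), payload_extra)
    res <- chem_backend(op, payload)
    .cache_put(keys[miss], res)
    hits[miss] <- res
  }
  hits
}

#' Clear the chemistry backend cache
#'
#' Drops all memoised backend results (standardization, fingerprints,
#' descriptors, SMARTS matches). Mainly useful in long sessions.
#' @return Invisibly, the number of entries removed.
#' @export
clear_chem_cache <- function() {
  n <- length(ls(.chem_cache))
  rm(list = ls(.chem_cache), envir = .chem_cache)
  invisible(n)
}
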