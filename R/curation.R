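# Chemical standardization and biological deduplication: raw entry tables ->
# curated binary / multiclass / continuous datasets per weight-of-evidence
# scheme or dose endpoint.

SCHEMES <- c("MLLP", "MSPE", "WoE", "WES")
ENDPOINTS <- c("dsa", "dsa05", "dsa01")

#' Standardize chemical structures
#'
#' Applies QSAR-ready standardization to raw SMILES: counterions and
#' carbon-free fragments are stripped, recognized organic counterions removed
#' when a parent organic remains, simple acids/bases neutralized (quaternary
#' nitrogens keep their charge), chemotypes normalized, and the result
#' canonicalized with stereochemistry preserved. Entries are rejected (never
#' erroring) as `mixture` (more than one distinct organic fragment),
#' `inorganic` (no carbon), `large_organic` (heavy atoms above `heavy_cap`) or
#' `unparsable`.
#'
#' Standardization is idempotent: feeding an accepted `std_smiles` back in
#' returns it unchanged.
#'
#' @param smiles Character vector of raw SMILES.
#' @param heavy_cap Maximum heavy-atom count before a structure is rejected
#'   as a large organic (polymer/macromolecule guard). Default 100.
#' @return A data.frame with columns `raw_smiles`, `status` (`"ok"` /
#'   `"rejected"`), `std_smiles` (NA when rejected) and `reason` (NA when ok;
#'   otherwise one of `mixture`, `inorganic`, `large_organic`, `unparsable`).
#' @examples \dontrun{
#' standardize_structure(c("CC(=O)[O-].[Na+]", "CCO.CCC", "[Na+].[Cl-]"))
#' }
#' @export
standardize_structure <- function(smiles, heavy_cap = 100) {
  stopifnot(length(smiles) >= 1)
  smiles <- as.character(smiles)
  smiles[is.na(smiles)] <- ""
  res <- .cached_backend("standardize", smiles,
                         extra_key = paste0("cap", heavy_cap),
                         payload_extra = list(heavy_cap = heavy_cap))
  data.frame(
    raw_smiles = smiles,
    status = vapply(res, function(r) r$status, ""),
    std_smiles = vapply(res, function(r) {
      if (identical(r$status, "ok")) r$std_smiles else NA_character_
    }, ""),
    reason = vapply(res, function(r) {
      if (identical(r$status, "ok")) NA_character_ else r$reason
    }, ""),
    stringsAsFactors = FALSE
  )
}

#' Standardize every record in a compound table
#'
#' Convenience wrapper around [standardize_structure()] that appends
#' `std_smiles`, `std_status` and `std_reason` columns to a record table read
#' by [read_compounds()] or produced by [simulate_compound_table()].
#'
#' @param records Data.frame with at least `casrn` and `smiles` columns.
#' @inheritParams standardize_structure
#' @return `records` with standardization columns added.
#' @export
standardize_records <- function(records, heavy_cap = 100) {
  stopifnot(is.data.frame(records), all(c("casrn", "smiles") %in% names(records)))
  std <- standardize_structure(records$smiles, heavy_cap = heavy_cap)
  records$std_smiles <- std$std_smiles
  records$std_status <- std$status
  records$std_reason <- std$reason
  records
}

.hazard_code <- function(outcome) {
  # hazard perspective: any sensitizer label counts as positive
  ifelse(outcome %in% c("1A", "1B", "sensitizer"), 1L,
         ifelse(outcome %in% "NC", 0L, NA_integer_))
}

.potency_code <- function(outcome) {
  ifelse(outcome %in% "1A", 2L,
         ifelse(outcome %in% "1B", 1L,
                ifelse(outcome %in% "NC", 0L, NA_integer_)))
}

.check_scheme <- function(records, scheme) {
  if (!scheme %in% names(records)) {
    stop("scheme '", scheme, "' not present in the record table")
  }
}

.empty_log <- function() {
  data.frame(casrn = character(), action = character(), reason = character(),
             stringsAsFactors = FALSE)
}

.log_rows <- function(casrn, action, reason) {
  if (!length(casrn)) return(.empty_log())
  data.frame(casrn = as.character(casrn), action = action, reason = reason,
             stringsAsFactors = FALSE)
}

#' Resolve duplicate structures within one outcome scheme
#'
#' Groups standardized records by canonical structure. A group whose informative
#' outcomes all agree is collapsed to one record (the extra rows are logged as
#' `deduplicated`); a group with disagreeing outcomes is removed entirely and
#' logged as `discordant`. Agreement is judged at `level = "hazard"`
#' (sensitizer vs non-sensitizer; 1A vs 1B agree) for binary work and at
#' `level = "potency"` (1A vs 1B disagree) for multiclass work.
#'
#' @param records Standardized record table (rows with `std_status == "ok"`).
#' @param scheme One of `"MLLP"`, `"MSPE"`, `"WoE"`, `"WES"`.
#' @param level `"hazard"` or `"potency"`.
#' @return List with `records` (deduplicated table) and `log` (drop log).
#' @export
resolve_duplicates <- function(records, scheme, level = c("hazard", "potency")) {
  level <- match.arg(level)
  .check_scheme(records, scheme)
  if (is.null(records$std_smiles) || anyNA(records$std_smiles)) {
    stop("records must be standardized (std_smiles present) before deduplication")
  }
  code_fun <- if (level == "hazard") .hazard_code else .potency_code
  codes <- code_fun(as.character(records[[scheme]]))
  keep <- logical(nrow(records))
  log <- .empty_log()
  for (smi in unique(records$std_smiles)) {
    idx <- which(records$std_smiles == smi)
    if (length(idx) == 1L) {
      keep[idx] <- TRUE
      next
    }
    grp_codes <- unique(codes[idx][!is.na(codes[idx])])
    if (length(grp_codes) > 1L) {
      log <- rbind(log, .log_rows(records$casrn[idx], "dropped", "discordant"))
    } else {
      # keep the first informative record (or plain first if none informative)
      informative <- idx[!is.na(codes[idx])]
      first <- if (length(informative)) informative[1L] else idx[1L]
      keep[first] <- TRUE
      rest <- setdiff(idx, first)
      log <- rbind(log, .log_rows(records$casrn[rest], "dropped", "duplicate"))
    }
  }
  list(records = records[keep, , drop = FALSE], log = log)
}

.new_dataset <- function(task, scheme, smiles, y, log) {
  structure(
    list(task = task, scheme = scheme,
         smiles = as.character(smiles), y = y, log = log),
    class = "ss_dataset"
  )
}

#' @export
print.ss_dataset <- function(x, ...) {
  cat("Curated ", x$task, " dataset (", x$scheme, "): ",
      length(x$smiles), " compounds\n", sep = "")
  if (x$task %in% c("binary", "multiclass")) {
    print(table(class = x$y))
  } else {
    cat("log10 dose range: [", round(min(x$y), 3), ", ",
        round(max(x$y), 3), "]\n", sep = "")
  }
  cat(nrow(x$log), "records dropped during curation\n")
  invisible(x)
}

#' Assemble a curated binary hazard dataset
#'
#' Maps outcomes for one weight-of-evidence scheme to 0/1 (NC -> 0; 1A, 1B and
#' plain "sensitizer" -> 1), dropping and logging records whose outcome is
#' unavailable or missing. Input must already be standardized and
#' deduplicated.
#'
#' @inheritParams resolve_duplicates
#' @return An `ss_dataset` of task `"binary"`.
#' @export
assemble_binary <- function(records, scheme) {
  .check_scheme(records, scheme)
  y <- .hazard_code(as.character(records[[scheme]]))
  drop <- is.na(y)
  log <- .log_rows(records$casrn[drop], "dropped", "unlabeled")
  if (all(drop)) stop("empty dataset: no labeled records for scheme ", scheme)
  .new_dataset("binary", scheme, records$std_smiles[!drop], y[!drop], log)
}

#' Assemble a curated multiclass potency dataset
#'
#' Maps outcomes to potency classes: NC -> 0, 1B (weak) -> 1, 1A (strong) -> 2.
#' Records with missing/unavailable outcomes (including plain "sensitizer"
#' entries that carry no potency information) are dropped and logged.
#'
#' @inheritParams resolve_duplicates
#' @return An `ss_dataset` of task `"multiclass"`.
#' @export
assemble_multiclass <- function(records, scheme) {
  .check_scheme(records, scheme)
  y <- .potency_code(as.character(records[[scheme]]))
  drop <- is.na(y)
  log <- .log_rows(records$casrn[drop], "dropped", "unlabeled")
  if (all(drop)) stop("empty dataset: no labeled records for scheme ", scheme)
  .new_dataset("multiclass", scheme, records$std_smiles[!drop], y[!drop], log)
}

#' Assemble a curated continuous dose dataset
#'
#' For one dose endpoint (`dsa`, `dsa05`, `dsa01`), takes the per-structure
#' median of the raw dose values (in micrograms per square centimetre) and
#' applies a base-10 logarithm. Records with missing doses are dropped and
#' logged; non-positive doses are dropped with reason `nonpositive_dose`.
#'
#' @param records Standardized record table (duplicate structures allowed;
#'   replicates feed the median).
#' @param endpoint One of `"dsa"`, `"dsa05"`, `"dsa01"`.
#' @return An `ss_dataset` of task `"continuous"` whose `y` holds
#'   log10(median dose).
#' @export
assemble_continuous <- function(records, endpoint = ENDPOINTS) {
  endpoint <- match.arg(endpoint)
  if (!endpoint %in% names(records)) {
    stop("endpoint '", endpoint, "' not present in the record table")
  }
  vals <- suppressWarnings(as.numeric(records[[endpoint]]))
  missing <- is.na(vals)
  nonpos <- !missing & vals <= 0
  log <- rbind(
    .log_rows(records$casrn[missing], "dropped", "missing_dose"),
    .log_rows(records$casrn[nonpos], "dropped", "nonpositive_dose")
  )
  use <- !missing & !nonpos
  if (!any(use)) stop("empty dataset: no usable dose values for ", endpoint)
  med <- tapply(vals[use], records$std_smiles[use], median)
  # replicate rows beyond the first per structure are consumed by the median
  first <- !duplicated(records$std_smiles[use])
  rep_casrn <- records$casrn[use][!first]
  log <- rbind(log, .log_rows(rep_casrn, "dropped", "replicate_median"))
  smi <- names(med)
  .new_dataset("continuous", endpoint, smi, as.numeric(log10(med)), log)
}

#' Run the full curation pipeline
#'
#' Standardizes structures, logs rejections, resolves duplicates (hazard-level
#' concordance for binary, potency-level for multiclass; replicate medians for
#' continuous), and assembles the curated dataset. The drop log accounts for
#' every input row: `nrow(records) == length(result$smiles) + nrow(result$log)`.
#'
#' @param records Raw record table (`casrn`, `smiles`, outcome/dose columns).
#' @param task `"binary"`, `"multiclass"` or `"continuous"`.
#' @param scheme Outcome scheme (binary/multiclass) or dose endpoint
#'   (continuous).
#' @inheritParams standardize_structure
#' @return An `ss_dataset`.
#' @export
curate_dataset <- function(records, task = c("binary", "multiclass", "continuous"),
                           scheme, heavy_cap = 100) {
  task <- match.arg(task)
  records <- standardize_records(records, heavy_cap = heavy_cap)
  bad <- records$std_status != "ok"
  log <- .log_rows(records$casrn[bad], "rejected", records$std_reason[bad])
  ok <- records[!bad, , drop = FALSE]
  if (!nrow(ok)) stop("empty dataset: no structure survived standardization")
  if (task == "continuous") {
    ds <- assemble_continuous(ok, scheme)
  } else {
    level <- if (task == "binary") "hazard" else "potency"
    dedup <- resolve_duplicates(ok, scheme, level = level)
    log <- rbind(log, dedup$log)
    ds <- if (task == "binary") assemble_binary(dedup$records, scheme)
          else assemble_multiclass(dedup$records, scheme)
  }
  ds$log <- rbind(log, ds$log)
  ds
}
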