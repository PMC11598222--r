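# Readers/writers and model-bundle persistence. CSV is the primary exchange
# format (UTF-8, header, comma-separated); SDF V2000 input is supported via
# ChemmineR. Model bundles are directories of JSON metadata plus an RDS
# predictor blob with an integrity digest.

BUNDLE_VERSION <- "1"

#' Read a compound record table
#'
#' CSV files must carry `casrn` and `smiles` columns, plus any of the four
#' outcome scheme columns (`MLLP`, `MSPE`, `WoE`, `WES`) and dose columns
#' (`dsa`, `dsa05`, `dsa01`). SDF input (V2000) takes the same fields from
#' the data block properties. Rows with an empty SMILES are skipped and
#' reported.
#'
#' @param path File path.
#' @param format `"csv"` or `"sdf"` (default: from the file extension).
#' @return Data.frame of records; attribute `skipped` counts malformed rows.
#' @export
read_compounds <- function(path, format = c("auto", "csv", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.sdf$", path, ignore.case = TRUE)) "sdf" else "csv"
  }
  if (format == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  } else {
    if (!requireNamespace("ChemmineR", quietly = TRUE)) {
      stop("SDF input requires the ChemmineR package")
    }
    sdf <- ChemmineR::read.SDFset(path)
    props <- ChemmineR::datablock2ma(ChemmineR::datablock(sdf))
    df <- as.data.frame(props, stringsAsFactors = FALSE)
    if (!"smiles" %in% names(df)) {
      stop("missing smiles column: SDF data blocks must carry a 'smiles' field")
    }
  }
  names(df) <- ifelse(tolower(names(df)) %in% c("casrn", "smiles", "dsa",
                                                "dsa05", "dsa01"),
                      tolower(names(df)), names(df))
  if (!"smiles" %in% names(df)) stop("missing smiles column in ", path)
  if (!"casrn" %in% names(df)) df$casrn <- sprintf("ROW-%05d", seq_len(nrow(df)))
  for (e in ENDPOINTS) {
    if (e %in% names(df)) df[[e]] <- suppressWarnings(as.numeric(df[[e]]))
  }
  bad <- is.na(df$smiles) | !nzchar(trimws(df$smiles))
  if (any(bad)) {
    message(sum(bad), " row(s) with empty SMILES skipped")
  }
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- sum(bad)
  out
}

#' Write a curated dataset and its drop log
#'
#' Emits `<stem>.csv` (std_smiles, label) and `<stem>_droplog.csv`
#' (casrn, action, reason).
#'
#' @param dataset An `ss_dataset`.
#' @param stem Output path stem.
#' @return The data CSV path, invisibly.
#' @export
write_dataset <- function(dataset, stem) {
  stopifnot(inherits(dataset, "ss_dataset"))
  data_path <- paste0(stem, ".csv")
  write.csv(data.frame(std_smiles = dataset$smiles, label = dataset$y),
            data_path, row.names = FALSE)
  write.csv(dataset$log, paste0(stem, "_droplog.csv"), row.names = FALSE)
  invisible(data_path)
}

#' Write a synthetic simulation (records CSV + ground-truth ledger JSON)
#'
#' @param sim An `ss_simulation` from [simulate_compound_table()].
#' @param dir Output directory (created if needed).
#' @return The records CSV path, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "ss_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec_path <- file.path(dir, "records.csv")
  write.csv(sim$records, rec_path, row.names = FALSE)
  jsonlite::write_json(
    list(truth = sim$truth,
         config = sim$config[setdiff(names(sim$config), "")],
         rules = sim$rules),
    file.path(dir, "ledger.json"), auto_unbox = TRUE, digits = NA)
  invisible(rec_path)
}

#' Save a fitted model bundle
#'
#' Writes a directory holding `meta.json` (algorithm, hyperparameters,
#' threshold, seeds, version, integrity digest), `selection.json`,
#' `scaler.json`, `ad.json` and the fitted predictor blob. [load_bundle()]
#' restores a model producing identical predictions, thresholds and domain
#' decisions.
#'
#' @param model An `ss_model`.
#' @param path Bundle directory.
#' @return `path`, invisibly.
#' @export
save_bundle <- function(model, path) {
  stopifnot(inherits(model, "ss_model"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  blob <- file.path(path, "predictor.rds")
  saveRDS(model[c("predictor", "pipeline", "ad", "calibration")], blob)
  digest <- unname(tools::md5sum(blob))
  meta <- list(version = BUNDLE_VERSION, task = model$task,
               scheme = model$scheme, feature_kind = model$feature_kind,
               algorithm = model$algorithm, params = model$params,
               pt = model$pt, Z = model$Z, seed = model$seed,
               classes = model$classes, n_train = length(model$train_smiles),
               digest = digest)
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  sels <- lapply(model$pipeline$selections, function(s) {
    list(method = s$method, indices = s$indices)
  })
  jsonlite::write_json(sels, file.path(path, "selection.json"), digits = NA)
  if (!is.null(model$pipeline$scaler)) {
    jsonlite::write_json(list(min = model$pipeline$scaler$min,
                              max = model$pipeline$scaler$max),
                         file.path(path, "scaler.json"), digits = NA)
  }
  jsonlite::write_json(list(d_bar = model$ad$d_bar, s = model$ad$s,
                            Z = model$ad$Z, cutoff = model$ad$cutoff,
                            n_reference = nrow(model$ad$reference)),
                       file.path(path, "ad.json"), auto_unbox = TRUE,
                       digits = NA)
  writeLines(model$train_smiles, file.path(path, "train_smiles.txt"))
  saveRDS(model$y, file.path(path, "labels.rds"))
  invisible(path)
}

#' Load a model bundle
#'
#' @param path Bundle directory written by [save_bundle()].
#' @return The restored `ss_model`.
#' @export
load_bundle <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) stop("not a model bundle: ", path)
  meta <- jsonlite::fromJSON(meta_path)
  if (!identical(as.character(meta$version), BUNDLE_VERSION)) {
    stop("bundle version mismatch: bundle has '", meta$version,
         "', this package reads '", BUNDLE_VERSION, "'")
  }
  blob <- file.path(path, "predictor.rds")
  digest <- unname(tools::md5sum(blob))
  if (!identical(digest, meta$digest)) {
    stop("bundle integrity check failed: predictor blob digest mismatch")
  }
  obj <- readRDS(blob)
  structure(
    list(task = meta$task, scheme = meta$scheme,
         feature_kind = meta$feature_kind, algorithm = meta$algorithm,
         params = as.list(meta$params), pipeline = obj$pipeline,
         predictor = obj$predictor, ad = obj$ad, pt = meta$pt,
         calibration = obj$calibration, seed = meta$seed, Z = meta$Z,
         train_smiles = readLines(file.path(path, "train_smiles.txt")),
         y = readRDS(file.path(path, "labels.rds")),
         classes = as.character(meta$classes)),
    class = "ss_model")
}

#' Batch prediction over raw SMILES
#'
#' Thin alias of [predict.ss_model()]: per-compound probability, calibrated
#' call, applicability-domain distance and flag; unparsable entries are
#' reported per row and never abort the batch.
#'
#' @param model An `ss_model`.
#' @param smiles Character vector of SMILES.
#' @return Prediction data.frame (one row per input).
#' @export
predict_batch <- function(model, smiles) {
  predict(model, smiles)
}

#' Write an out-of-fold prediction table
#'
#' @param cv An `ss_cv`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cv_predictions <- function(cv, path) {
  stopifnot(inherits(cv, "ss_cv"))
  write.csv(cv$oof, path, row.names = FALSE)
  invisible(path)
}
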