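# Synthetic compound-and-outcome generator. Emulates the structure of human
# patch-test compound tables — small organics with structural-alert driven
# sensitization classes, class imbalance favoring sensitizers, injected
# salts/mixtures/duplicates, per-scheme outcome maps with occasional
# discordance, and log-scale dose values with high per-compound variability —
# so that every pipeline stage can be exercised offline.

#' Default structural alert rules
#'
#' Alert substructures chosen for their relevance to the skin-sensitization
#' adverse outcome pathway (direct or metabolically activated electrophiles):
#' aldehydes act as strong alerts; sulfonamides and 1,2-alkane diols as weak
#' alerts. Each rule carries an activation probability (1 = deterministic).
#'
#' @return Data.frame with `name`, `smarts`, `effect` (`"strong"`/`"weak"`),
#'   `probability`.
#' @export
default_alert_rules <- function() {
  data.frame(
    name = c("aldehyde", "sulfonamide", "diol12"),
    smarts = c("[CX3H1](=O)[#6]",
               "[SX4](=[OX1])(=[OX1])[NX3]",
               "[OX2H][CX4][CX4][OX2H]"),
    effect = c("strong", "weak", "weak"),
    probability = c(1, 1, 1),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic data generator
#'
#' Defaults describe the study conditions the generator emulates: 400
#' entries, sensitizer-skewed class mix (non/weak/strong = 0.22/0.60/0.18,
#' i.e. roughly 3.5:1 sensitizers to non-sensitizers with weak sensitizers
#' about three times as abundant as either other class), 5% exact duplicate
#' entries, 10% salt forms, 3% two-component mixtures, 5% label noise, and
#' class-ordered log10 dose distributions (strong sensitizers potent at low
#' doses) with a fraction of compounds carrying 2-5 replicate dose entries of
#' inflated spread.
#'
#' @param n Total entries (>= 20).
#' @param seed Integer seed.
#' @param class_probs Named class mix (`nc`, `weak`, `strong`); must sum to 1.
#' @param duplicate_fraction Fraction of entries that exactly duplicate
#'   another entry.
#' @param salt_fraction Fraction of entries emitted as salt forms.
#' @param mixture_fraction Fraction of entries emitted as two-component
#'   mixtures.
#' @param label_noise Per-structure probability of a random class flip.
#' @param discordance_rate Probability that a duplicate entry carries one
#'   corrupted outcome scheme (to exercise discordant-duplicate removal).
#' @param unavailable_rate Per-entry-per-scheme probability of an
#'   "unavailable" outcome.
#' @param dose_log_mean Named log10 dose means (ug/cm2) per class.
#' @param dose_log_sd Log10 dose standard deviation.
#' @param replicate_fraction Fraction of structures receiving replicate dose
#'   entries.
#' @param replicate_sd_factor Spread inflation for replicate entries.
#' @return List of class `ss_synth_config`.
#' @export
synthetic_config <- function(n = 400, seed = 7,
                             class_probs = c(nc = 0.22, weak = 0.60,
                                             strong = 0.18),
                             duplicate_fraction = 0.05,
                             salt_fraction = 0.10,
                             mixture_fraction = 0.03,
                             label_noise = 0.05,
                             discordance_rate = 0.5,
                             unavailable_rate = 0.02,
                             dose_log_mean = c(strong = 0.5, weak = 1.5,
                                               nc = 2.5),
                             dose_log_sd = 0.4,
                             replicate_fraction = 0.2,
                             replicate_sd_factor = 2.5) {
  stopifnot(n >= 20, abs(sum(class_probs) - 1) < 1e-8,
            all(c("nc", "weak", "strong") %in% names(class_probs)))
  fr <- c(duplicate_fraction, salt_fraction, mixture_fraction, label_noise,
          discordance_rate, unavailable_rate, replicate_fraction)
  stopifnot(all(fr >= 0 & fr <= 1))
  structure(as.list(environment()), class = "ss_synth_config")
}

# scaffold templates ({R}, {Q} = substituent slots) and substituent pools
.synth_templates <- function() {
  list(
    one = c("c1ccc({R})cc1", "C1CCC({R})CC1", "CCCCC{R}", "CCCCCCC{R}",
            "CC(C)C{R}", "c1ccnc({R})c1"),
    two = c("c1ccc({R})c({Q})c1", "C1CCC({R})C({Q})C1")
  )
}

.synth_substituents <- function() {
  list(
    benign = c("C", "CC", "CCC", "OC", "O", "Cl", "Br", "F", "C#N",
               "C(=O)OC", "N(C)C", "C(F)(F)F"),
    weak = c("S(=O)(=O)N", "S(=O)(=O)NC", "S(=O)(=O)NCC", "S(=O)(=O)N(C)C",
             "C(O)CO", "CC(O)CO", "C(O)C(C)O", "CCC(O)CO"),
    strong = c("C=O", "CC=O", "CCC=O", "C(C)C=O")
  )
}

.fill <- function(template, r, q = NULL) {
  out <- sub("{R}", r, template, fixed = TRUE)
  if (!is.null(q)) out <- sub("{Q}", q, out, fixed = TRUE)
  out
}

# enumerate the full scaffold x substituent space (raw SMILES, unique)
.enumerate_space <- function() {
  tpl <- .synth_templates()
  subs <- unlist(.synth_substituents(), use.names = FALSE)
  singles <- unlist(lapply(tpl$one, function(t) {
    vapply(subs, function(r) .fill(t, r), "")
  }))
  pairs <- unlist(lapply(tpl$two, function(t) {
    idx <- which(upper.tri(matrix(0, length(subs), length(subs)), diag = TRUE),
                 arr.ind = TRUE)
    vapply(seq_len(nrow(idx)), function(i) {
      .fill(t, subs[idx[i, 1]], subs[idx[i, 2]])
    }, "")
  }))
  unique(c(singles, pairs))
}

# match alert rules; returns the alert-implied class per structure
.alert_class <- function(smiles, rules) {
  res <- .cached_backend("smarts", smiles,
                         extra_key = paste(rules$smarts, collapse = "|"),
                         payload_extra = list(patterns = as.list(rules$smarts)))
  vapply(res, function(r) {
    if (is.null(r)) return(NA_character_)
    hit <- vapply(r, function(m) m$n_matches > 0, TRUE)
    if (any(hit & rules$effect == "strong")) "strong"
    else if (any(hit & rules$effect == "weak")) "weak"
    else "nc"
  }, "")
}

#' Generate a synthetic raw SMILES library
#'
#' Enumerates scaffold-substituent combinations (benzene, cyclohexane,
#' pyridine and chain scaffolds; benign, weak-alert and strong-alert
#' substituents), classifies each by structural alert, and draws a seeded
#' sample matching the configured class mix. Exact duplicates, salt forms
#' (appended hydrochloride fragment) and two-component mixtures are injected
#' at the configured fractions.
#'
#' @param config An [synthetic_config()].
#' @param rules Alert rules (default [default_alert_rules()]).
#' @return Character vector of `config$n` raw SMILES with attribute `truth`:
#'   a data.frame with `entry`, `structure_id`, `kind`
#'   (`"base"`/`"duplicate"`/`"mixture"`), `salted` and `alert_class`.
#' @export
generate_library <- function(config = synthetic_config(),
                             rules = default_alert_rules()) {
  stopifnot(inherits(config, "ss_synth_config"))
  n <- config$n
  n_dup <- round(config$duplicate_fraction * n)
  n_mix <- round(config$mixture_fraction * n)
  n_base <- n - n_dup - n_mix
  space <- .enumerate_space()
  std <- standardize_structure(space)
  ok <- std$status == "ok" & !duplicated(std$std_smiles)
  space <- space[ok]
  cls <- .alert_class(space, rules)
  pools <- split(space, cls)
  rng <- .restore_seed_state(); on.exit(rng())
  set.seed(config$seed)
  want <- as.vector(stats::rmultinom(1, n_base,
                                     config$class_probs[c("nc", "weak",
                                                          "strong")]))
  names(want) <- c("nc", "weak", "strong")
  for (k in names(want)) {
    if (want[[k]] > length(pools[[k]])) {
      stop("n exceeds enumerable space for class '", k, "' (need ",
           want[[k]], ", have ", length(pools[[k]]), ")")
    }
  }
  base <- unlist(lapply(names(want), function(k) {
    sample(pools[[k]], want[[k]])
  }))
  base <- sample(base)  # shuffle class blocks
  dup_src <- if (n_dup > 0) sample(seq_len(n_base), n_dup, replace = TRUE)
             else integer(0)
  mixtures <- if (n_mix > 0) {
    vapply(seq_len(n_mix), function(i) {
      paste(sample(base, 2), collapse = ".")
    }, "")
  } else character(0)
  smiles <- c(base, base[dup_src], mixtures)
  kind <- c(rep("base", n_base), rep("duplicate", n_dup),
            rep("mixture", n_mix))
  structure_id <- c(seq_len(n_base), dup_src,
                    if (n_mix) n_base + seq_len(n_mix) else integer(0))
  n_salt <- round(config$salt_fraction * n)
  saltable <- which(kind != "mixture")
  salted <- rep(FALSE, n)
  if (n_salt > 0) {
    pick <- sample(saltable, min(n_salt, length(saltable)))
    smiles[pick] <- paste0(smiles[pick], ".Cl")
    salted[pick] <- TRUE
  }
  truth <- data.frame(entry = seq_len(n), structure_id = structure_id,
                      kind = kind, salted = salted,
                      stringsAsFactors = FALSE)
  attr(smiles, "truth") <- truth
  smiles
}

#' Assign outcome labels to a synthetic library
#'
#' Labels every entry from its structural alerts (strong alert -> strong
#' sensitizer 1A, weak alert -> weak sensitizer 1B, none -> NC), applies
#' per-structure Bernoulli label noise, then fills the four
#' weight-of-evidence outcome columns. Duplicate entries can carry one
#' corrupted scheme (at the configured discordance rate) to exercise
#' discordant-duplicate removal; a small per-entry-per-scheme fraction of
#' outcomes is set to "unavailable".
#'
#' @param smiles Library from [generate_library()] (with its `truth`
#'   attribute) or any character vector of SMILES.
#' @param rules Alert rules.
#' @param config An [synthetic_config()].
#' @return Data.frame of records: `casrn`, `smiles`, scheme columns
#'   (`MLLP`, `MSPE`, `WoE`, `WES`), with attribute `truth` extended by
#'   `true_class` and per-scheme discordance flags.
#' @export
assign_outcomes <- function(smiles, rules = default_alert_rules(),
                            config = synthetic_config()) {
  n <- length(smiles)
  truth <- attr(smiles, "truth")
  if (is.null(truth)) {
    truth <- data.frame(entry = seq_len(n), structure_id = seq_len(n),
                        kind = "base", salted = FALSE,
                        stringsAsFactors = FALSE)
  }
  rng <- .restore_seed_state(); on.exit(rng())
  set.seed(config$seed + 1L)
  acls <- .alert_class(as.character(smiles), rules)
  # activation probability: an alert class may stochastically fail to fire
  p_act <- setNames(rules$probability, rules$effect)
  to_num <- c(nc = 0L, weak = 1L, strong = 2L)
  # per-structure label: duplicates inherit their source structure's label
  sid <- truth$structure_id
  lab <- to_num[acls]
  for (s in unique(sid)) {
    rows <- which(sid == s)
    l <- lab[rows[1]]
    if (l > 0) {
      eff <- if (l == 2L) "strong" else "weak"
      pa <- min(p_act[names(p_act) == eff], 1)
      if (length(pa) && runif(1) > pa) l <- 0L
    }
    if (runif(1) < config$label_noise) {
      l <- sample(setdiff(0:2, l), 1)
    }
    lab[rows] <- l
  }
  out_label <- c("NC", "1B", "1A")[lab + 1L]
  casrn <- sprintf("SYN-%05d", sid)
  rec <- data.frame(casrn = casrn, smiles = as.character(smiles),
                    stringsAsFactors = FALSE)
  discord <- matrix(FALSE, n, length(SCHEMES),
                    dimnames = list(NULL, SCHEMES))
  for (sch in SCHEMES) {
    col <- out_label
    is_dup <- truth$kind == "duplicate"
    flip <- is_dup & runif(n) < (config$discordance_rate / length(SCHEMES))
    if (any(flip)) {
      col[flip] <- vapply(col[flip], function(l) {
        sample(setdiff(c("NC", "1B", "1A"), l), 1)
      }, "")
      discord[flip, sch] <- TRUE
    }
    unav <- runif(n) < config$unavailable_rate
    col[unav] <- "unavailable"
    rec[[sch]] <- col
  }
  truth$true_class <- lab
  for (sch in SCHEMES) truth[[paste0("discordant_", sch)]] <- discord[, sch]
  attr(rec, "truth") <- truth
  rec
}

#' Assign dose-per-skin-area values to labeled records
#'
#' Draws log10 doses per class from the configured normal distributions
#' (strong sensitizers potent at the lowest doses), and gives a configured
#' fraction of structures 2-5 replicate entries with inflated spread,
#' reproducing the wide per-compound dose variability of real patch-test
#' data. DSA05 and DSA01 are emitted as correlated scalings of DSA.
#'
#' @param records Record table from [assign_outcomes()].
#' @param config An [synthetic_config()].
#' @return Records with `dsa`, `dsa05`, `dsa01` columns; replicate entries
#'   appended as extra rows (flagged in the `truth` attribute).
#' @export
assign_doses <- function(records, config = synthetic_config()) {
  truth <- attr(records, "truth")
  stopifnot(!is.null(truth), nrow(truth) == nrow(records))
  rng <- .restore_seed_state(); on.exit(rng())
  set.seed(config$seed + 2L)
  cls_name <- c("nc", "weak", "strong")[truth$true_class + 1L]
  mu <- config$dose_log_mean[cls_name]
  draw <- function(mu, sd) 10^rnorm(length(mu), mu, sd)
  records$dsa <- draw(mu, config$dose_log_sd)
  records$dsa05 <- records$dsa * 10^rnorm(nrow(records), -0.3, 0.1)
  records$dsa01 <- records$dsa * 10^rnorm(nrow(records), -0.6, 0.1)
  # replicate dose entries with inflated spread for a fraction of structures
  base_rows <- which(truth$kind == "base")
  n_rep <- round(config$replicate_fraction * length(base_rows))
  if (n_rep > 0) {
    picks <- sample(base_rows, n_rep)
    extra <- lapply(picks, function(i) {
      k <- sample(2:5, 1)
      sd_i <- config$dose_log_sd * config$replicate_sd_factor
      rows <- records[rep(i, k), , drop = FALSE]
      rows$dsa <- draw(rep(mu[i], k), sd_i)
      rows$dsa05 <- rows$dsa * 10^rnorm(k, -0.3, 0.1)
      rows$dsa01 <- rows$dsa * 10^rnorm(k, -0.6, 0.1)
      rows
    })
    extra_truth <- truth[rep(picks, vapply(extra, nrow, 0L)), , drop = FALSE]
    extra_truth$kind <- "dose_replicate"
    records <- rbind(records, do.call(rbind, extra))
    truth <- rbind(truth, extra_truth)
    truth$entry <- seq_len(nrow(truth))
    rownames(records) <- NULL
  }
  attr(records, "truth") <- truth
  records
}

#' Simulate a complete synthetic compound table
#'
#' Runs the full generator — library, outcomes, doses — and returns the
#' record table in the same schema the curation reader consumes, together
#' with a ground-truth ledger for reconciliation tests.
#'
#' @param config An [synthetic_config()].
#' @param rules Alert rules.
#' @param doses Include dose columns and replicate dose entries (default
#'   TRUE).
#' @return List of class `ss_simulation`: `records` (data.frame) and `truth`
#'   (ledger data.frame, one row per record row).
#' @export
simulate_compound_table <- function(config = synthetic_config(),
                                    rules = default_alert_rules(),
                                    doses = TRUE) {
  lib <- generate_library(config, rules)
  rec <- assign_outcomes(lib, rules, config)
  if (doses) rec <- assign_doses(rec, config)
  truth <- attr(rec, "truth")
  attr(rec, "truth") <- NULL
  structure(list(records = rec, truth = truth, config = config,
                 rules = rules),
            class = "ss_simulation")
}

#' @export
print.ss_simulation <- function(x, ...) {
  cat("Synthetic compound table:", nrow(x$records), "entries (",
      sum(x$truth$kind == "base"), "base,",
      sum(x$truth$kind == "duplicate"), "duplicates,",
      sum(x$truth$kind == "mixture"), "mixtures,",
      sum(x$truth$kind == "dose_replicate"), "dose replicates )\n")
  cat("True class mix:\n")
  print(table(x$truth$true_class[x$truth$kind == "base"]))
  invisible(x)
}
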