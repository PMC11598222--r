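test_that("library generation is reproducible with exact injection counts", {
  cfg <- synthetic_config(n = 100, seed = 11, duplicate_fraction = 0.1,
                          mixture_fraction = 0.04, salt_fraction = 0.08)
  lib1 <- generate_library(cfg)
  lib2 <- generate_library(cfg)
  expect_identical(lib1, lib2)
  truth <- attr(lib1, "truth")
  expect_length(lib1, 100)
  expect_equal(sum(truth$kind == "duplicate"), 10)
  expect_equal(sum(truth$kind == "mixture"), 4)
  expect_equal(sum(truth$salted), 8)
  # duplicates reference existing base structures
  dup <- truth[truth$kind == "duplicate", ]
  expect_true(all(dup$structure_id <= sum(truth$kind == "base")))
  # no salts, no mixtures: single-fragment entries only
  clean <- generate_library(synthetic_config(n = 60, seed = 3,
                                             salt_fraction = 0,
                                             mixture_fraction = 0,
                                             duplicate_fraction = 0))
  expect_false(any(grepl("\\.", clean)))
  expect_error(generate_library(synthetic_config(n = 5000, seed = 1)),
               "enumerable space")
})

test_that("outcomes follow structural alerts with configured noise", {
  cfg <- synthetic_config(n = 80, seed = 5, label_noise = 0,
                          duplicate_fraction = 0, mixture_fraction = 0,
                          salt_fraction = 0, unavailable_rate = 0)
  lib <- generate_library(cfg)
  rec <- assign_outcomes(lib, config = cfg)
  truth <- attr(rec, "truth")
  cls <- skinsens:::.alert_class(as.character(lib), default_alert_rules())
  # noise 0: labels equal the alert classes exactly
  expect_equal(truth$true_class,
               unname(c(nc = 0L, weak = 1L, strong = 2L)[cls]))
  expect_equal(unname(rec$WES[truth$true_class == 2][1]), "1A")
  expect_true(all(rec$WES[truth$true_class == 0] == "NC"))
})

test_that("the study-scale class mix lands near the configured imbalance", {
  sim <- study_sim()
  base <- sim$truth[sim$truth$kind == "base", ]
  tab <- table(factor(base$true_class, levels = 0:2))
  n <- sum(tab)
  # binary sensitizer:non-sensitizer imbalance within +-20% of 3.5:1
  ratio <- (tab[["1"]] + tab[["2"]]) / tab[["0"]]
  expect_gt(ratio, 0.8 * 3.5 * 0.8)   # generous band, binomial concentration
  expect_lt(ratio, 3.5 * 1.4)
  # weak sensitizers roughly three times the other classes
  expect_gt(tab[["1"]] / tab[["2"]], 2)
  expect_gt(tab[["1"]] / tab[["0"]], 2)
})

test_that("dose assignment orders classes and reproduces replicate spread", {
  cfg <- synthetic_config(n = 200, seed = 9)
  sim <- simulate_compound_table(cfg)
  truth <- sim$truth
  dose <- log10(sim$records$dsa)
  m_strong <- mean(dose[truth$true_class == 2])
  m_weak <- mean(dose[truth$true_class == 1])
  m_nc <- mean(dose[truth$true_class == 0])
  expect_lt(m_strong, m_weak)   # more potent = sensitizing at lower dose
  expect_lt(m_weak, m_nc)
  expect_true(any(truth$kind == "dose_replicate"))
  # zero spread collapses all same-class doses to the class mean
  cfg0 <- synthetic_config(n = 50, seed = 2, dose_log_sd = 0,
                           replicate_fraction = 0, label_noise = 0,
                           duplicate_fraction = 0, mixture_fraction = 0)
  sim0 <- simulate_compound_table(cfg0)
  d0 <- log10(sim0$records$dsa[sim0$truth$true_class == 1])
  expect_lt(diff(range(d0)), 1e-9)
  # reproducible end to end
  sim0b <- simulate_compound_table(cfg0)
  expect_identical(sim0$records, sim0b$records)
})

test_that("curation removes exactly the injected mixtures and discordant duplicates", {
  sim <- small_sim()
  truth <- sim$truth
  ds <- curate_dataset(sim$records, "binary", "WES")
  log <- ds$log
  # every injected mixture is rejected as a mixture
  mix_casrn <- sim$records$casrn[truth$kind == "mixture"]
  expect_true(all(mix_casrn %in% log$casrn[log$reason == "mixture"]))
  expect_equal(sum(log$reason == "mixture"), length(mix_casrn))
  # hazard-discordant duplicate groups are dropped as discordant
  hazard <- function(l) ifelse(l %in% c("1A", "1B"), 1L,
                               ifelse(l == "NC", 0L, NA_integer_))
  discordant_structs <- unique(unlist(lapply(
    split(seq_len(nrow(sim$records)), truth$structure_id),
    function(rows) {
      if (length(rows) < 2) return(NULL)
      h <- unique(na.omit(hazard(sim$records$WES[rows])))
      if (length(h) > 1) truth$structure_id[rows[1]] else NULL
    })))
  got_discordant <- unique(log$casrn[log$reason == "discordant"])
  want_discordant <- unique(sim$records$casrn[truth$structure_id %in%
                                                discordant_structs])
  expect_setequal(got_discordant, want_discordant)
})
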