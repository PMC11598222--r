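test_that("standardization strips salts, rejects mixtures/inorganics, and is idempotent", {
  std <- standardize_structure(c(
    "CC(=O)[O-].[Na+]",  # sodium acetate -> neutral acetic acid
    "CCO.CCC",           # two comparable organics -> mixture
    "[Na+].[Cl-]",       # no carbon -> inorganic
    "CCO",
    "xx(",               # unparsable, never an exception
    "C1CCCCC1C=O.Cl"     # hydrochloride fragment stripped
  ))
  expect_equal(std$status, c("ok", "rejected", "rejected", "ok", "rejected", "ok"))
  expect_equal(std$std_smiles[1], "CC(=O)O")
  expect_equal(std$reason[2:3], c("mixture", "inorganic"))
  expect_equal(std$reason[5], "unparsable")
  # idempotence: restandardizing accepted output returns it unchanged
  ok <- std$std_smiles[std$status == "ok"]
  expect_equal(standardize_structure(ok)$std_smiles, ok)
})

test_that("heavy-atom cap rejects large organics and is configurable", {
  long_chain <- paste(rep("C", 120), collapse = "")
  expect_equal(standardize_structure(long_chain)$reason, "large_organic")
  expect_equal(standardize_structure(long_chain, heavy_cap = 200)$status, "ok")
})

make_records <- function(casrn, smiles, wes) {
  standardize_records(data.frame(casrn = casrn, smiles = smiles, WES = wes,
                                 stringsAsFactors = FALSE))
}

test_that("duplicate resolution keeps concordant groups and removes discordant ones", {
  rec <- make_records(c("A1", "A2", "B"), c("CCO", "OCC", "CCC"),
                      c("1A", "1B", "NC"))
  # hazard level: 1A vs 1B agree (both sensitizers) -> one record kept
  rh <- resolve_duplicates(rec, "WES", level = "hazard")
  expect_equal(nrow(rh$records), 2)
  expect_equal(rh$log$reason, "duplicate")
  # potency level: 1A vs 1B disagree -> whole group removed
  rp <- resolve_duplicates(rec, "WES", level = "potency")
  expect_equal(sort(rp$records$casrn), "B")
  expect_true(all(rp$log$reason == "discordant"))
  # truly discordant hazard outcomes -> removed
  rec2 <- make_records(c("C1", "C2"), c("CCO", "OCC"), c("1A", "NC"))
  rh2 <- resolve_duplicates(rec2, "WES", level = "hazard")
  expect_equal(nrow(rh2$records), 0)
  # all distinct -> unchanged
  rec3 <- make_records(c("D", "E"), c("CCO", "CCC"), c("1A", "NC"))
  expect_equal(nrow(resolve_duplicates(rec3, "WES")$records), 2)
  expect_error(resolve_duplicates(rec3, "MLLP"), "MLLP")
})

test_that("binary assembly maps hazard labels and drops unlabeled entries", {
  rec <- make_records(c("A", "B", "C", "D"), c("CCO", "CCC", "CCCC", "CCCCC"),
                      c("sensitizer", "NC", "unavailable", "1B"))
  ds <- assemble_binary(rec, "WES")
  expect_equal(ds$y, c(1, 0, 1))
  expect_equal(ds$log$casrn, "C")
  # 1A and 1B are both sensitizers from a hazard perspective
  rec2 <- make_records(c("X", "Y"), c("CCO", "CCC"), c("1A", "1B"))
  expect_equal(assemble_binary(rec2, "WES")$y, c(1, 1))
  rec3 <- make_records("Z", "CCO", "unavailable")
  expect_error(assemble_binary(rec3, "WES"), "empty dataset")
})

test_that("multiclass assembly maps NC/1B/1A to 0/1/2 and accounts for every record", {
  rec <- make_records(c("A", "B", "C", "D"), c("CCO", "CCC", "CCCC", "CCCCC"),
                      c("1A", "1B", "NC", "missing"))
  ds <- assemble_multiclass(rec, "WES")
  expect_equal(ds$y, c(2, 1, 0))
  expect_equal(nrow(rec), length(ds$y) + nrow(ds$log))
  expect_equal(sum(table(ds$y)), length(ds$smiles))
})

test_that("continuous assembly takes per-structure medians then log10", {
  rec <- standardize_records(data.frame(
    casrn = c("A1", "A2", "A3", "B", "C", "D"),
    smiles = c("CCO", "CCO", "OCC", "CCC", "CCCC", "CCCCC"),
    dsa = c(10, 100, 1000, 1, NA, -5), stringsAsFactors = FALSE))
  ds <- assemble_continuous(rec, "dsa")
  vals <- setNames(ds$y, ds$smiles)
  expect_equal(unname(vals["CCO"]), 2)         # median(10,100,1000) = 100
  expect_equal(unname(vals["CCC"]), 0)         # log10(1) = 0
  expect_true("nonpositive_dose" %in% ds$log$reason)
  expect_true("missing_dose" %in% ds$log$reason)
  # even-sized replicate list: median is the midpoint mean
  rec2 <- standardize_records(data.frame(
    casrn = c("E1", "E2"), smiles = c("CCO", "CCO"), dsa = c(10, 1000),
    stringsAsFactors = FALSE))
  expect_equal(assemble_continuous(rec2, "dsa")$y, log10(505))
})

test_that("full curation conserves records, is order invariant and idempotent", {
  sim <- small_sim()
  ds <- curate_dataset(sim$records, "binary", "WES")
  expect_equal(nrow(sim$records), length(ds$smiles) + nrow(ds$log))
  # order invariance: permuting input changes neither items nor labels
  set.seed(42)
  perm <- sample(nrow(sim$records))
  ds2 <- curate_dataset(sim$records[perm, ], "binary", "WES")
  m1 <- setNames(ds$y, ds$smiles)
  m2 <- setNames(ds2$y, ds2$smiles)
  expect_equal(m1[sort(names(m1))], m2[sort(names(m2))])
  # idempotence: identical result on a rerun
  ds3 <- curate_dataset(sim$records, "binary", "WES")
  expect_identical(ds$smiles, ds3$smiles)
  expect_identical(ds$y, ds3$y)
  expect_identical(ds$log, ds3$log)
})
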