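# skinsens

QSAR modeling of **human skin sensitization** from patch-test derived
compound tables.

Human predictive patch tests (repeat insult patch tests, maximization
tests) are the most relevant evidence for whether a chemical causes
allergic contact dermatitis, but the data are scarce, noisy, duplicated,
and heavily skewed toward sensitizers. `skinsens` is an R package for
scientists who need to turn such tables into defensible structure-based
classifiers: it curates raw entries, fits calibrated models with an
explicit applicability domain, explains predictions down to individual
atoms, and characterizes the activity landscape of continuous dose data.

## What it does

* **Curation** — RDKit-backed structure standardization (salt stripping,
  neutralization, canonicalization; mixtures/inorganics/oversized organics
  rejected with reasons), hazard- or potency-level duplicate resolution,
  and assembly of binary (sensitizer = 1 vs NC = 0), multiclass
  (NC/1B/1A → 0/1/2) and continuous (log10 median dose-per-skin-area)
  datasets per weight-of-evidence scheme, with a complete drop log.
* **Modeling** — ECFP4 / MACCS fingerprints or a continuous descriptor
  block; low-variance filtering, recursive feature elimination and
  fold-isolated min–max scaling (descriptors); random forest, leaf-wise
  gradient boosting, or RBF SVM with Platt-scaled probabilities; Bayesian
  hyperparameter search (GP surrogate + expected improvement, default
  configuration always trial 0); stratified 5-fold *external*
  cross-validation; Y-randomization.
* **Calibration** — threshold moving: the binary cutoff PT maximizes the
  geometric mean √(SE·SP) over the pooled out-of-fold predictions (exact
  scan over observed probabilities; ties favor sensitivity).
* **Applicability domain** — Euclidean 1-NN domain with cutoff
  D_c = d̄ + Z·s (Z = 0.5 default) in the model's own feature space;
  metrics are reported in-domain with coverage alongside.
* **Interpretation** — exactly additive per-feature attributions
  (tree-path decomposition for forests) and atom-level fragment
  contribution maps: an atom's weight is the probability drop when the
  fingerprint bits containing it are zeroed; rendered as green/purple SVG
  depictions.
* **Landscape & chemical space** — ROGI roughness of activity landscapes
  (complete-linkage coarse-graining), metric MDS with interpolated
  activity grids, and UMAP + DBSCAN chemical-space grouping.
* **Synthetic data** — a seeded structural-alert generator
  (aldehyde/sulfonamide/1,2-diol alerts, configurable class imbalance,
  duplicates, salts, mixtures, label noise, replicate dose spread) that
  emulates the *shape* of patch-test tables so the whole pipeline is
  testable offline.

Core metrics follow the field's definitions: SE, SP, CCR = (SE+SP)/2,
PPV, NPV, rank AUC; macro one-vs-rest for multiclass; undefined metrics
are `NA`, never 0.

## Worked example

```r
library(skinsens)

# a synthetic patch-test table: 400 entries, alert-driven labels,
# duplicates/salts/mixtures injected (generator defaults)
sim <- simulate_compound_table(synthetic_config(n = 400, seed = 7))
ds  <- curate_dataset(sim$records, "binary", "WES")
ds
#> Curated binary dataset (WES): 358 compounds
#> class
#>   0   1
#>  85 273
#> 288 records dropped during curation

cv <- ss_crossval(ds, feature_kind = "ecfp4",
                  algorithm = "random_forest", seed = 1)
cv
#> 5-fold external cross-validation (binary WES, ecfp4 + random_forest)
#>   pooled (in-domain): CCR=0.964 SE=0.989 SP=0.938 PPV=0.979 NPV=0.968 AUC=0.946
#>   coverage: 70.7%; PT = 0.5
```

358 of the 400+ entries survive curation (the rest are mixtures,
discordant duplicates, replicate dose rows and unlabeled entries — all
itemized in `ds$log`), with the configured ~3.5:1 sensitizer skew. The
cross-validated model recovers the alert signal almost completely
(CCR 0.96 over the 70.7% of out-of-fold compounds inside the
applicability domain), and here calibration keeps the default threshold
(PT = 0.5 already maximizes the geometric mean).

```r
model <- ss_fit(ds, "ecfp4", "random_forest", seed = 1, pt = cv$pt)
predict(model, c("CCCCCC=O", "NS(=O)(=O)c1ccccc1", "CCCCCC"))
#>               smiles     prob_1 call ad_distance in_ad
#> 1           CCCCCC=O 0.93448891    1           1  TRUE
#> 2 NS(=O)(=O)c1ccccc1 0.97557563    1           0  TRUE
#> 3             CCCCCC 0.02708226    0           1  TRUE
```

Hexanal (an aldehyde) and benzenesulfonamide are called sensitizers with
high probability; hexane is not. All three sit inside the domain cutoff.
The atom-level map shows *why* hexanal is called positive:

```r
atom_contributions(model, "CCCCCC=O")
#> Atom contribution map for CCCCCC=O
#>   P(class 1) = 0.934
#>  atom symbol weight
#>     0      C -0.075
#>     ...
#>     5      C  1.000
#>     6      O  0.945
```

The carbonyl carbon and oxygen — the aldehyde alert — carry the large
positive weights: zeroing their fingerprint bits collapses the predicted
sensitization probability. `render_contribution_map()` draws this as a
green/purple depiction.

A command-line front end over the same functions is installed at
`system.file("cli", "skinsens.R", package = "skinsens")` with verbs
`simulate`, `curate`, `crossvalidate`, `train`, `predict`, `yrandomize`,
`interpret`, `landscape`, `chemspace`.

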