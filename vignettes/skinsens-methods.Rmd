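---
title: "Modeling human skin sensitization from patch-test outcomes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling human skin sensitization from patch-test outcomes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Skin sensitization — the ability of a chemical to induce allergic contact
dermatitis — is a routine endpoint in chemical safety assessment. Human
predictive patch testing (repeat insult patch tests and maximization tests)
provides the most relevant evidence, but ethical constraints keep such data
scarce, noisy, and heavily skewed toward positives: substances suspected to
be harmless are rarely tested at sensitizing doses, so clean negatives are
structurally under-represented. `skinsens` implements a complete QSAR
pipeline for this setting: it turns raw compound/outcome tables into curated
datasets, fits calibrated classifiers for hazard (sensitizer vs not) and
potency (GHS 1A strong / 1B weak / NC non-sensitizer), restricts claims to an
explicit applicability domain, explains predictions down to individual
atoms, and characterizes the activity landscape of continuous
dose-per-skin-area (DSA) data.

Because real patch-test collections cannot be redistributed with a package,
`skinsens` ships a synthetic data generator that reproduces the *statistical
shape* of such collections, so that every stage of the pipeline is testable
offline (see "What the generator emulates" below).

## Curation

Raw tables carry a CAS registry number, a SMILES, up to four
weight-of-evidence outcome columns (MLLP, MSPE, WoE, WES) with labels in
{NC, 1B, 1A, sensitizer, unavailable}, and optional dose values (DSA,
DSA05, DSA01, µg/cm²).

**Chemical standardization** (via the bundled RDKit backend) strips
carbon-free fragments and a fixed dictionary of common organic counterions,
neutralizes simple charged acids/bases (quaternary nitrogens keep their
charge), normalizes chemotypes, and canonicalizes with stereochemistry
preserved. Entries are rejected — never silently fixed — as `mixture` (more
than one distinct organic fragment), `inorganic` (no carbon),
`large_organic`, or `unparsable`. Two deliberately conservative choices:

* *Mixtures vs salts.* Only recognized counter**ions** are strippable.
  Neutral organic co-fragments (e.g. an ethanol/propane pair) make the entry
  a mixture: stripping solvents would silently change the tested substance.
* *Size cap.* The large-organic cutoff is a heavy-atom count (default 100,
  configurable). It is meant to exclude polymers and macromolecules while
  keeping every plausible patch-test chemical; no published cutoff exists
  for this data, so the value is a package default, not a data-derived one.

**Biological deduplication** groups records by canonical structure. A group
whose outcomes agree is collapsed to one record; a group with conflicting
outcomes is removed entirely — keeping either record would inject label noise
of exactly the kind that inflates or deflates cross-validated performance.
Agreement is judged from a *hazard* perspective for binary work (1A vs 1B
agree: both are sensitizers) but from a *potency* perspective for multiclass
work (1A vs 1B disagree). Continuous endpoints instead take the
per-structure **median** of replicate doses and then log10: the median is
robust to the very wide per-compound spread these assays show.

Every dropped row is logged with a reason, and curation conserves records
exactly: input rows = curated items + logged drops.

## Features

* **ECFP4** (2048-bit extended-connectivity fingerprints, diameter 4; the
  same computation as radius-2 Morgan fingerprints used for chemical-space
  work) and **MACCS** keys (167 positions, index 0 unused by convention).
* A **continuous descriptor block**: RDKit's 2-D physicochemical descriptor
  set (~210 descriptors). Descriptors that are non-finite for any training
  compound are dropped and recorded in the selection state.

Selection and scaling are deliberately asymmetric between the two feature
families:

* All models get a **low-variance filter** (population variance > 0.01; for
  a fingerprint bit with on-fraction *p* this is *p*(1−*p*), so bits present
  in fewer than ~1% of compounds fall out).
* Descriptor models additionally get **recursive feature elimination**
  (impurity-importance ranking from a small forest, dropping the lowest 10%
  of remaining features per round; default target = half the post-filter
  features) and **min–max scaling** to [0, 1]. Fingerprint bits are never
  scaled and never RFE-selected: bit identity is the substrate of the
  atom-level interpretation, and binary bits need no scaling.
* Everything is fitted **per training fold only**. Held-out rows may scale
  outside [0, 1]; there is no clipping, and perturbing a held-out compound
  can never change any fitted state.

## Models, tuning, and validation

Three algorithm families cover the common tabular-QSAR trade-offs: a
probability random forest (`ranger`), leaf-wise gradient boosting
(`xgboost` with lossguide growth), and an RBF SVM (`e1071`). SVM
probabilities come from in-package Platt scaling on the decision values
(one-vs-rest with renormalization for multiclass); this keeps SVM
predictions deterministic for a given seed.

Hyperparameters are searched with a compact Bayesian optimizer written for
this package: the library-default configuration is always trial 0, the next
trials come from a seeded Latin-hypercube design, and the remainder are
proposed by a Gaussian-process surrogate (RBF kernel on the unit cube,
fixed length-scale 0.3) maximizing expected improvement. The objective is
mean CCR over a stratified 3-fold inner cross-validation *of the training
split*, so tuning never sees external folds, and the returned configuration
is by construction never worse than the default under that objective.
Search spaces: forest size 100–1000 / depth 3–30; boosting leaves 15–255,
learning rate 10⁻³–0.3, rounds 100–1000 (log-scaled); SVM C 10⁻²–10³,
γ 10⁻⁴–10 (log-scaled).

**External validation** is stratified 5-fold cross-validation: per fold, the
entire pipeline (featurization, selection, scaling, applicability domain,
tuning, training) is refitted on the 80% split and the 20% split is scored
once. Stratification is a package choice the data forces: at a few hundred
compounds with a 3–4:1 class skew, plain random folds occasionally lose a
class from a training split. Multiclass datasets are randomly undersampled —
the majority class reduced to the runner-up class size — on the training
side of each fold, so no test compound is ever discarded by balancing.

Metrics are the field's standard set: SE, SP, CCR = (SE+SP)/2, PPV, NPV,
rank-based AUC, with one-vs-rest macro averaging for multiclass. A metric
with a zero denominator is reported as *undefined* (`NA`), excluded from
macro averages, and never silently zero. The CCR identity is maintained in
every report the package emits.

**Y-randomization** refits the whole cross-validation on shuffled labels
(independent derived seeds, 10 rounds by default); a real model must beat
every shuffled run, whose CCR should hover near 0.5.

## Threshold moving

Imbalanced training data depresses minority-class probabilities, so the
conventional 0.5 cutoff wastes sensitivity or specificity. For binary
models the package selects the probability threshold maximizing
√(SE·SP) — the geometric mean, which punishes lopsided errors — on the
*pooled out-of-fold* predictions, yielding one threshold per model. The
candidate set is the observed unique probabilities plus 0.5: the geometric
mean is piecewise constant between observed values, so this scan is exact
and dominates any fixed grid. Ties break toward the smallest threshold,
which favors sensitivity — the costlier error direction in sensitization
screening is the missed sensitizer. Calibration can never lose to the
default cutoff on the selection set, since 0.5 is always a candidate.

## Applicability domain

The domain is the classic nearest-neighbor construction: for each training
compound, the Euclidean distance to its nearest training neighbor (1-NN by
default; exposed as a parameter); a query is in-domain when its distance to
the nearest training compound is at most D_c = d̄ + Z·s, with Z = 0.5 by
default. The exact threshold formula of the original workflow tooling is
not published; d̄ + Z·s over within-training 1-NN distances is the standard
construction of that lineage and is documented and configurable here. The
domain lives in the same post-selection (and, for descriptors, post-scaling)
space the model consumes — "reliable region" is only meaningful in the
model's own input space. Out-of-domain compounds are still predicted but
flagged; reported metrics cover in-domain compounds, with coverage (% inside)
reported alongside.

## Interpretation

Two complementary views:

* **Per-feature attributions.** Random forests are explained by exact path
  decomposition: walking each tree root→leaf, the change in the node's
  expected probability at every split is credited to the split feature.
  The telescoping sum makes base + Σφ equal the forest probability to
  machine precision. Gradient boosting uses the booster's own exact tree
  contributions (log-odds scale, documented on the result). SVMs are
  explained by seeded permutation sampling against training background
  rows; the telescoping construction again keeps additivity exact while
  individual values are sampling estimates. (Exact Shapley values for
  kernel models are out of scope; the path decomposition is exact-additive
  rather than exact-Shapley, which is the tractable point in this
  trade-off and is stated on the object.)
* **Atom-level contribution maps.** For each atom, the fingerprint bits
  whose circular environments contain that atom are zeroed (a
  hash-collision-shared bit belongs to every owning atom) and the atom's
  weight is P(full) − P(bits removed): positive weights mark substructures
  pushing the prediction toward sensitization. Weights are normalized by
  the per-molecule maximum absolute value — the natural scale-free choice
  when no normalization formula is prescribed — and are invariant to input
  SMILES ordering because the structure is canonicalized first. Maps render
  to SVG with the field's color convention (green toward, purple against
  sensitization). Bits are zeroed, not recomputed on a fragment: recomputing
  would create a different (often invalid) molecule rather than ablate the
  atom's evidence.

## Activity landscape and chemical space

Continuous DSA data are analysed rather than modeled (regression on these
endpoints is not attempted; the per-compound variability of the underlying
assays makes dose prediction unreliable, and the landscape analysis below
shows why). On min–max-normalized descriptors, all-pairs Euclidean
distances are rescaled to [0, 1] and the **roughness index (ROGI)** is
computed: activity is min–max normalized; for every complete-linkage merge
height *t* (plus 0 and 1) the dataset is coarse-grained to size-weighted
cluster means and the weighted dispersion σ(t) recorded; the score is
2·∫(σ(0) − σ(t))dt by trapezoid. Smooth landscapes lose dispersion slowly
(low ROGI); activity cliffs collapse it early (high ROGI). Constant
activity gives exactly 0, the score is invariant to positive affine
activity transforms, and the degenerate all-equal-distances case returns
the maximal value 2σ(0) with a warning.

Visualization projects the distance matrix to 2-D by classical metric MDS
(deterministic, so the seed argument is recorded rather than consumed) and
interpolates activity over a regular grid by inverse-distance weighting —
exact at the data points and bounded by the observed activity range;
collinear configurations are rejected. Chemical-space grouping uses
radius-2/2048-bit Morgan fingerprints, the variance filter, a seeded UMAP
embedding (Jaccard metric), and DBSCAN on the embedding (minimum group
size 3; radius from the 90th percentile of k-distance, the usual knee
heuristic; noise points get group 0). Compounds are embedded in
canonical-SMILES sort order so the partition is invariant to input order.

## What the synthetic generator emulates — and what it does not

`simulate_compound_table()` enumerates a scaffold × substituent space
(benzene, cyclohexane, pyridine, chains; benign plus alert substituents)
and samples it with seeded randomness. Its defaults are the study
conditions used throughout the tests: 400 entries; class mix 0.22 / 0.60 /
0.18 (non / weak / strong), i.e. roughly 3.5:1 sensitizers to
non-sensitizers with weak sensitizers about three times as abundant as
either other class; 5% label noise; 5% exact duplicates (half carrying one
corrupted outcome scheme to exercise discordant-duplicate removal); 10%
salt forms; 3% two-component mixtures; and class-ordered log10 dose
distributions (means 0.5 / 1.5 / 2.5 log µg/cm² for strong / weak / non,
SD 0.4) with 20% of structures receiving 2–5 replicate dose entries at 2.5×
spread, reproducing the wide per-compound dose variability of real data.
Labels follow three structural alerts chosen for their relevance to the
sensitization adverse-outcome pathway (direct or activatable electrophiles):
aldehyde (strong), sulfonamide and 1,2-alkane-diol (weak) — which also makes
the atom-attribution tests mechanistically meaningful.

What passing tests on this generator show: the pipeline recovers a
structure-encoded signal through curation noise, duplicates, salts and
mixtures; calibration, domain gating, attribution and landscape machinery
all behave per contract. What they do not show: performance on real
patch-test chemistry. Real collections are more diverse, their "alerts" are
soft and context-dependent, and their negatives are scarcer and noisier;
absolute CCR on the synthetic set (≈0.95) is far above what real data
support and must not be read as a performance claim.

## Numerical choices and degenerate inputs

* Variance uses the population (1/n) definition, matching the p(1−p)
  reading of a bit's variance.
* A feature constant on the training fold min–max scales to 0 everywhere.
* Threshold application is boundary-inclusive (call positive iff p ≥ PT).
* Tie-breaks: threshold scan → smallest candidate; argmax class calls →
  first class in order; RFE drops the lowest-importance block, minimum one
  feature per round.
* Single-class training folds are skipped with a warning (cross-validation)
  or are an error (direct training).
* The applicability domain of duplicated training rows degenerates to
  D_c = 0: only exact matches are in-domain, which is the honest reading.
* Probability forests and boosters emit float32-rounded rows; multiclass
  probabilities are renormalized to sum to exactly 1.
* Seeded helpers save and restore the caller's RNG state, so package calls
  never perturb user-level reproducibility.

## Problem sizes

The test-suite and acceptance-script study sizes are the package's chosen
defaults: the synthetic study set at n = 400 (≈360 curated compounds),
5-fold cross-validation with library-default hyperparameters (tuning is
exercised separately at small n), 10 Y-randomization rounds, 50 molecules
for the atom-attribution check, 100 rows for the additivity check, and
three ~370-compound dose sets for the landscape analysis. These sizes keep
a full run in the low minutes on one CPU while leaving every statistical
conclusion comfortably away from its acceptance band.

## Known limitations

* The chemistry backend shells out to Python RDKit; a Python environment
  with `rdkit` (and `umap-learn` for embeddings) must be on the PATH as
  `python` (override with the `SKINSENS_PYTHON` environment variable).
* MACCS keys have no bit→atom environment mapping, so atom-level maps are
  limited to circular fingerprints.
* SVM attributions are sampling approximations (additivity is exact, the
  per-feature split is approximate).
* UMAP embeddings are reproducible for a fixed seed and version but not
  stable across umap-learn versions.
* No CASRN→structure resolution: structures must be supplied.
* Continuous dose prediction is deliberately out of scope; the package
  provides the landscape analysis that explains why.
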