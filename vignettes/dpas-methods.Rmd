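---
title: "Anomaly scoring of disease-associated peptides: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anomaly scoring of disease-associated peptides: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Collections of disease-associated peptides — for example mutated-peptide
databases mined from proteomics — are *positive-only*: there is no
experimentally validated set of non-disease peptides to train against.
Supervised classifiers trained on manufactured negatives inherit whatever
bias went into manufacturing them. `dpas` instead fits one-class models to
the positive class and scores each peptide by how far it deviates from the
learned distribution, then fuses that anomaly score with a feature
attribution term into a single ranking score (DPAS) used to prioritize
peptides for downstream annotation.

```{r setup}
library(dpas)
```

## Sequence descriptors

Every peptide is mapped to a fixed, named feature vector. Blocks, in
order:

| block | width | definition |
|---|---|---|
| `AAC_*` | 20 | fraction of each amino acid, `count / length` |
| `GRP_*` | 11 | `AAC` aggregated over an 11-group reduced alphabet |
| `Volume_Measure` | 1 | mean residue volume (Kharakoz estimates, Å³) |
| `Hydrophobicity_Measure` | 1 | mean Hopp–Woods hydrophilicity |
| `PCP_*` | 5 | fractions in 5 physicochemical classes |
| `SER` | 1 | Shannon entropy (bits) of the composition |
| `RRI_*` | 20 | length-normalized counts, gated at count ≥ 2 |
| `DPC_*` | 400 | adjacent-pair frequencies, `count / (length − 1)` |
| `MOTIF_*` | m | binary motif occurrence (optional) |

The non-motif panel is 459 columns. All composition blocks are simplex
valued (non-negative, sum to 1); the two scale means are bounded by the
scale's extremes; entropy lies in `[0, log2 20]`.

Three descriptor definitions required a choice, because the tools that
popularized them publish names rather than formulas:

* **Grouped composition.** The 11-group membership of the reduced
  alphabet is not standardized in print. The package ships a documented
  default (aliphatic IVLM, aromatic FWY, hydroxyl ST, amide NQ, acidic
  DE, basic KR, and singletons A, G, C, P, H) as a named
  `grouping_scheme`; any 11-group file can be dropped in via
  `read_grouping_scheme()` without touching downstream code.
* **Physicochemical classes.** Likewise a documented default: positive
  {K, R, H}, negative {D, E}, hydrophobic {A, C, F, I, L, M, V, W},
  hydrophilic {N, Q, S, T, Y}, neutral {G, P}; overridable the same way.
* **Shannon entropy.** "Entropy at residue level" is ambiguous between a
  per-position series and a per-sequence scalar. We compute the scalar
  entropy of the whole-sequence composition, the standard reading for a
  fixed-width feature vector.

The two numeric scales ship as commented TSVs under
`inst/extdata/scales/` so they are versioned and swappable; the test
suite pins their checksums.

Lowercase letters in input sequences (mutated-peptide databases often
print the mutated residue in lowercase) are preserved in `raw_sequence`
and upper-cased for all feature math; no feature depends on case, because
the case semantics are not formally defined by the upstream databases.

## Motif features

Motif occurrence is a binary block, either from scanning PROSITE-style
patterns (`[ST]-P`, `C-x(2)-C`, anchors `<`/`>`, negated classes `{P}`)
compiled to regular expressions, or from an external MAST-style hit table
of `(sample_id, motif_id, evalue)` rows. For hit tables the default marks
a motif present when its best E-value is **at or below** the threshold —
the universal significance convention. The inverse reading ("higher than
the threshold") can be requested with `evalue_direction = "ge"` for
compatibility, but scoring *insignificant* matches as present is almost
certainly not what an analysis wants, so it is not the default. Motifs
with no hits stay 0, and the block width always equals the number of
motifs supplied — no fixed motif count is assumed.

## One-class models and the common scoring contract

All scorers obey one contract: `anomaly_scores(model, matrix)` returns
one finite score per sample with **higher = more anomalous**. Native
conventions that point the other way (the one-class SVM decision value,
the isolation forest's path-length score) are negated inside the wrapper.
Scores are compared across models after min–max normalization to
`[0, 1]`; a constant score vector maps to all zeros.

* **Standardization** uses the population (1/n) standard deviation;
  features with `sd < 1e-12` are recorded as constant and mapped to 0,
  never divided by.
* **PCA** (`fit_pca`) retains either a fixed k or the smallest k reaching
  a variance fraction (default 0.95). Its reconstruction error — the
  squared residual after projecting onto the retained components — is
  itself one of the four scorers.
* **One-class SVM** wraps the ν-parameterized SVM (default ν = 0.05,
  RBF kernel). The kernel width defaults to the variance-scaled
  convention `1 / (p · var(X))`: a fixed `1/p` saturates the kernel on
  inputs with large feature variance (PCA scores), at which point all
  distant samples tie at the boundary constant and their relative order
  is numerical noise.
* **Isolation forest** is implemented in-package (100 trees, subsample
  `min(256, n)`, depth cap `⌈log2 ψ⌉`, the standard `2^(−E[h]/c(ψ))`
  score). Its behavior was cross-checked against a reference
  implementation during development: scores agree in regime, including
  the less flattering regimes described below.
* **Autoencoder**: a small fully connected MLP, `p → ⌈p/2⌉ → ⌈p/4⌉ →
  ⌈p/2⌉ → p`, tanh hidden units, linear output, full-batch Adam for 50
  epochs (50 is deliberately conservative to avoid memorizing the
  outliers present in the training set). The learning rate defaults to
  0.02 — the largest tried step at which the training loss still
  decreases monotonically; 0.01 visibly underconverges within 50 epochs
  and 0.1 oscillates. Weight initialization is seeded, training is
  deterministic given seed + data. The raw score is the per-sample mean
  squared reconstruction error.

### How models are routed through PCA

`fit_dpas_model()` standardizes, optionally PCA-reduces, then fits. The
default routing (`pca_variance = "auto"`) sends the SVM and the
autoencoder through the 95%-variance PCA but fits the isolation forest
on the standardized features directly. The reason is structural:
isolation trees split on one axis at a time, so an anomaly signal that
PCA rotates into a handful of components among dozens of retained noise
components is visited too rarely to shorten the outliers' paths, and the
forest's ranking degrades — a known failure mode of axis-aligned
ensembles in rotated spaces, reproduced by the reference implementation
as well. Trees need no decorrelation, so they simply skip the rotation.

### Thresholding

The outlier threshold is a percentile (default 95) of the normalized
scores of the scored set, computed with linear interpolation between
order statistics (`quantile(type = 7)`); samples **strictly above** the
threshold are labeled −1 (outliers), everything else +1. By
construction this flags roughly 5% of any continuously scored set, which
is exactly the behavior the acceptance script measures at n = 1000.
Below 20 samples the function warns that a 95th percentile is coarse.
Absolute thresholds (e.g. a fixed reconstruction-error cut) are
deliberately not hard-coded: they are artifacts of a particular dataset
and scale, while the percentile rule transfers.

## Feature importance and the DPAS ranking

`feature_importance()` is a model-agnostic permutation attribution: for
each feature, each round replaces the column with a permutation of its
background values and records each sample's absolute change in raw
anomaly score; attributions average over rounds (default 3–5), and
global importance averages attributions over samples. This is the same
"perturb the input, watch the prediction" contract as SHAP-style
explanation, without the Shapley weighting — exact Shapley values over
459 features and arbitrary one-class scorers are not computable at this
scale, and the spec of the ranking only needs a stable, seeded,
monotone attribution. A feature the model ignores (or one constant
across the background) attributes ≈ 0; duplicated columns attribute
comparably.

Because `fit_dpas_model()` objects score *raw* feature matrices through
the whole standardize → PCA → model chain, attributions are expressed in
the original named feature space (`PCP_*`, `MOTIF_*`, ...), not in PCA
coordinates.

The ranking score is the exact weighted sum

```
DPAS = α · normalized anomaly score + β · importance term
```

with user weights α, β ≥ 0 (defaults 0.5/0.5; the weighting is
inherently a user decision). The importance term is per-sample — the mean
absolute attribution over the top-k globally important features (k = 3
by default), min–max normalized so both terms share `[0, 1]`. A *global*
importance constant would shift every DPAS equally and change no rank;
the per-sample term is what makes β meaningful. Ranks are dense,
1-based, by decreasing DPAS, with ties broken lexicographically by
sample id so output is stable across runs. `select_top()` exports the
top n (default 15) as FASTA for external annotation.

## Synthetic data and the validation experiment

`generate_peptides(synthetic_spec())` builds the test fixture standing in
for a real mutated-peptide set: by default 100 inliers drawn
residue-by-residue from a broad, natural-like composition (with a
`[ST]-P` motif planted into half of them) and 5 outliers drawn from a
composition confined to {C, W, H, M, P}, lengths 8–15, all under one
seed (byte-reproducible FASTA). The effect size is deliberately large —
disjoint compositions — because the fixture's job is to verify that
every scorer *recovers planted structure with the right direction*, not
to estimate power on realistic effect sizes. What passing these tests
shows about real data is therefore limited: real disease-associated
outliers differ far more subtly, and ranking quality there depends on
feature relevance, not on the mechanics verified here. Ground-truth
labels are emitted as a sidecar table, never parsed from FASTA headers,
so the one-class path stays label-blind.

`permute_columns()` builds synthetic negatives by shuffling each feature
column independently (each column gets its own draw from the seeded
stream): marginals are preserved exactly — per-column sorted values are
identical — while dependencies between features are destroyed. A single
shared row permutation would preserve the joint rows and defeat the
purpose.

`run_validation_experiment()` splits the positives *first* (70/30,
stratified construction) and permutes within each split. Permuting the
pooled positives would place feature values of test-set positives inside
the training negatives; with a kernel classifier this leaks enough
similarity to invert generalization (we observed test accuracies far
*below* chance before adopting the split-first construction). The two
baselines are an RBF SVM and a "supervised autoencoder" — the anomaly
autoencoder's bottleneck encodings with a logistic classification head,
the minimal faithful reading of an autoencoder used as a binary
classifier. The positive:negative ratio is 1:1 by construction;
evaluation reports per-class precision/recall/F1 plus accuracy.

## Problem sizes and numerical choices

The test fixture is 100 + 5 peptides (459 features, ~90 retained
components); the acceptance script uses 1000 peptides. Both complete in
seconds to a couple of minutes on a single CPU, which is ample for the
properties being measured — the flagged fraction at a percentile
threshold is forced analytically and does not sharpen with larger n.

Degenerate inputs are handled explicitly rather than by accident:
constant features standardize to 0; constant score vectors normalize to
0; all-equal scores produce zero outliers; an all-constant feature
matrix aborts the validation experiment with a clear error; a 1-residue
peptide is an error when dipeptide composition is enabled (it has no
dipeptides), or skipped under `--skip-invalid`.

## Known limitations

* The grouped-composition and physicochemical memberships are documented
  defaults, not canonical tables; swap in the published grouping if you
  have it.
* Permutation attribution is not Shapley-exact; correlated features
  share credit in ways that depend on the background.
* The isolation forest's *ranking among inliers* is seed-sensitive in
  high dimensions (the reference implementation behaves the same); only
  the inlier/outlier separation is stable, which is what the pipeline
  uses.
* PCA reconstruction error cannot flag outliers that dominate the
  training variance — their direction is retained and they reconstruct
  perfectly. It is included as a scorer because it is cheap and
  interpretable, but on contaminated training sets the other three
  models are the right tools.
* The α, β weighting of DPAS is a user decision; no default can claim
  optimality.
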