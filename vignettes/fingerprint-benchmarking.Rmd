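---
title: "Benchmarking molecular fingerprints: models, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking molecular fingerprints: models, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`fpbench` compares rule-based and data-driven molecular fingerprints on
three tasks: drug-combination response regression, representation
similarity, and class-based clustering. This vignette documents the models
it implements, the parameters that matter, the synthetic study the package
validates itself on, and the design decisions taken where the methodology
was genuinely open.

## Standardization and graph featurization

SMILES input is canonicalized with OpenBabel; salts and solvents are
stripped by keeping the largest fragment by heavy-atom count, with ties
broken by the lexicographically smallest canonical string — the simplest
reproducible reading of desalting. The 8–140 character filter is applied to
the *standardized* string, since filtering logically follows
standardization.

Each molecule becomes a graph: binary symmetric adjacency `A` (bond
presence only), the self-loop normalization
`A_norm = D^(-1/2) (A + I) D^(-1/2)` (so every entry lies in (0, 1] where
`A + I` is non-zero and an isolated atom maps to the 1×1 matrix `[1]`), and
a 54-column one-hot node matrix: 38 atom-type slots (37 named elements plus
an unknown slot that absorbs anything else), 6 degree bins (0–5), 5
formal-charge bins (−2…+2), 4 chirality variants (unspecified, CW, CCW,
other) and an aromaticity flag. Every row therefore sums to 4, or 5 for
aromatic atoms. The 37-element list is a configurable default of common
druglike elements; membership only affects one-hot routing, never
dimensions. Out-of-range degrees or charges are clamped to the nearest bin
with a warning rather than rejected, because a single exotic atom should
not invalidate a molecule.

Per-atom annotations (aromaticity, formal charge, tetrahedral chirality)
are read from the canonical SMILES string itself, because OpenBabel's SDF
export does not carry formal charge or stereo parity in the atom block;
the SDF supplies bonds, and the two atom orders coincide by construction.

## Rule-based fingerprints

Morgan (circular) fingerprints use the extended-connectivity construction
at radius 2 — the community default (ECFP4-equivalent) since no radius is
canonical — folded by modular hashing to 300 or 1024 bits. Topological
fingerprints are OpenBabel's 1024-bit path-based FP2 (linear fragments up
to seven atoms). Both are deterministic for a fixed toolkit version and
invariant to SMILES atom ordering. A 3D circular fingerprint requires
conformer generation, which no shipped backend provides; the adapter slot
raises a typed capability error unless the user supplies a generator, and
core functionality never depends on it.

## Graph autoencoder and the singular-value fingerprint

The encoder is seven graph-convolution layers, each a sum aggregation over
`A_norm` (`H ← ReLU(A_norm H W)`). Two readings of "convolution with sum
pooling" exist; a *global* sum pooling after each layer would collapse the
per-node embedding matrix that the fingerprint construction needs, so the
per-node (permutation-equivariant) reading is the only consistent one. The
embedding width is fixed at 16: the 64-bit pooled fingerprint concatenates
three pooled blocks with the 16 singular values, and 3·16 + 16 = 64 forces
it. Hidden widths between the 54 input features and the 16-dimensional
embedding are not prescribed anywhere, so the default interpolates
geometrically (54→48→40→36→32→24→20→16) and is configurable.

The decoder is `sigmoid(Z Zᵀ)` with 0.1 dropout on the logits during
training; the loss is elementwise binary cross-entropy with the entries of
`A_norm` as soft targets (a binary-adjacency target is available as a
config alternative). With soft targets the loss floor is the mean target
entropy, reached exactly at perfect reconstruction.

The 16-bit fingerprint is the descending diagonal of Σ from the SVD of the
molecule's embedding matrix, zero-padded when the molecule has fewer than
16 atoms. Because `A_norm`-aggregation is permutation-equivariant and
singular values are invariant to row permutation, the fingerprint is
invariant to node relabeling end to end — a property the test suite asserts
on random relabelings. The Frobenius identity `Σσᵢ² = ‖Z‖²_F` holds whenever
|V| ≤ 16 and becomes an inequality under truncation. A per-molecule SVD is
the only reading compatible with zero-padding "short" Σ diagonals; an SVD
of a stacked multi-molecule matrix would always have 16 singular values.

## SMILES variational autoencoder

The encoder maps one-hot characters (vocabulary built from the training
corpus plus a reserved pad token at index 1) through three 1D convolutions
of widths 9, 9 and 10 with SELU activations into dense heads for the
posterior mean and log-variance; the decoder repeats the sampled latent
vector at every timestep through three GRU layers (hidden width 501 by
default) and a time-distributed softmax. The loss is an equally weighted
sum of elementwise binary cross-entropy and the KL divergence to the
standard-normal prior; weights are Xavier-uniform initialized. The
*fingerprint* is the posterior mean μ, never a sample: downstream
consumers need deterministic representations. Characters unseen at
inference map to the pad slot with a warning.

Both trainable models share one protocol: Adam from a learning rate of
1e-3, halving on any epoch that fails to improve the loss (patience 1, the
simplest schedule satisfying the init/floor contract), halting at 1e-6 or
at zero loss, inside a k-fold loop (default 5) that carries one set of
weights across folds. Training is bitwise reproducible under the config
seed on a single device, and a non-finite loss aborts with diagnostics.
Graphs are processed per molecule within minibatches (gradient
accumulation), which is arithmetically identical to zero-padding a batch to
its largest molecule and masking the padded entries out of the loss.

**Problem sizes.** The package's own training demonstrations and tests run
at desk scale, a deliberate choice of study size: the GAE smoke run uses 20
molecules for 5 epochs, and the VAE smoke run uses 200 SMILES for 3 epochs
with a reduced GRU hidden width of 64. The architecture defaults (hidden
501, input length 140) are unchanged; only the exercised problem sizes are
small, and both runs must still reduce their loss from initialization and
reproduce bitwise under a fixed seed.

## HSIC and CKA

For column-centered matrices under the linear kernel the feature-space
statistic `‖YᵀX‖²_F` and the sample-space statistic `trace(XXᵀYYᵀ)`
coincide; the package implements both and asserts their agreement to 1e-9
relative. CKA normalizes HSIC into [0, 1]. The default estimator is the
unbiased U-statistic (zeroed diagonals, three-term combination with the
1/(m(m−3)) prefactor, requiring m ≥ 4); its published form is only defined
on Gram matrices, so the unbiased path always uses sample space, while the
biased path honors the feature-vs-sample efficiency rule (feature space
when compounds outnumber bits). Unbiased estimates can be slightly
negative on independent data: the CKA numerator is clamped at zero (raw
values are retained in the `SimilarityResult`), and a constant matrix —
whose self-HSIC vanishes — raises an "undefined similarity" error instead
of returning NaN. Binary fingerprints are cast to reals and centered
exactly like continuous ones, which is what makes cross-family comparison
meaningful. For the plug-in estimator linear CKA equals the RV
coefficient, which the tests compute independently as an oracle.

## Regression benchmark

Tuples are canonicalized by sorted compound id — the data model treats
(A,B) and (B,A) as the same experiment, and canonicalization guarantees
order invariance end to end (an augmentation mode emitting both orders is
available) — then replicate scores are averaged within each (pair, cell
line) key. Pair featurization concatenates the two fingerprints in
canonical order with the cell-line one-hot; topological fingerprints are
bit-averaged instead (elementwise mean), halving their block width.

The 90:10 protocol is plain k-fold cross-validation (k = 10). A "10-fold"
60:40 split is internally inconsistent — ten disjoint folds cannot each
hold 40% of the data — so it is implemented as ten repeated shuffled 60:40
holdouts, matching both stated numbers as closely as possible. Fold
correlations feed a Fisher-z Student-t interval (df = folds − 1,
back-transformed endpoints); the aggregation level (fold-wise PCCs) is a
package choice. The Shapiro–Wilk test is applied to the z-transformed fold
PCCs — the quantity the t-interval actually assumes normal — and warns
below p = 0.05 without blocking. Normalized RMSE divides by the population
(n-denominator) SD so that the constant-mean predictor scores exactly 1;
its interval is a symmetric empirical bootstrap (1000 paired resamples,
±97.5th percentile of absolute deviations). The regressor is a pluggable
fit/predict pair — gradient-boosted trees (xgboost) as the shipped
default, ridge and OLS as baselines — with one model per score.

## Clustering evaluation

Fingerprint matrices are z-scored (population SD; constant columns
dropped with a warning), then optionally reduced by PCA (smallest leading
set of components exceeding 0.95 cumulative explained variance) or by PLS
with the one-hot class labels as the multivariate target (K − 1 components
by default, matching the discriminative dimensionality of K classes). "One-
versus-all LDA clustering" is implemented as: per class, fit a binary
(class vs. rest) linear discriminant, project all points on its axis, score
that 1D projection by Silhouette and the variance ratio criterion with the
binary labels as clusters, and average over the K problems — the only
construction that jointly honors "one-versus-all", "LDA" and per-
fingerprint scalar scores. Scoring the projections (rather than the
preprocessed features with LDA as a mere classifier) is the adopted
reading. A singular within-class scatter is ridge-regularized with a
warning. Silhouette uses Euclidean distance; singleton clusters and
coincident points (max(a, b) = 0) score 0 by convention. Zero within-
cluster variance makes the VRC infinite, reported as an `Inf` sentinel
with a flag. Raw scores are min–max scaled per metric within each
preprocessing regime — so each regime column attains both 1 and 0 — and
fingerprints are ranked by the z-score-regime results (silhouette first,
VRC as tie-break).

## The synthetic study

The molecule generator composes valid SMILES from a fragment grammar:
chain units (alkyl, ether, amine, carbonyl, ester, amide), chiral and
charged bracket fragments, one of 12 ring-scaffold families (recorded per
molecule), and a terminal unit. About 2% of molecules are deliberately
emitted below 8 characters and 2% above 140 so the length filter is
exercised; everything else parses and survives standardization.

Screens plant a known signal: a latent response linear in interpretable
pair descriptors (heavy-atom, aromatic, heteroatom, halogen, charge and
chirality counts — deliberately *not* any shipped fingerprint, so no
method is trivially favored) plus a cell-line effect, standardized and
mixed with Gaussian noise so the variance fraction explained by
structure + cell line equals ρ exactly in the generative model. The five
scores are affine transforms of this latent with partially shared noise
(`interScoreCor` controls the shared fraction), at score scales loosely
mimicking typical sensitivity/synergy magnitudes. The attainable PCC
ceiling for a regressor given the true descriptors is therefore √ρ, which
the recovery tests check at ρ = 0.49 (ceiling 0.7) and at ρ = 0 (interval
must cover zero). Class labels follow the scaffold families (merged
round-robin into K classes and deterministically rebalanced so every class
has at least two members), making them structure-correlated by
construction.

What the generator does *not* emulate: real pharmacology, dose–response
surfaces, the marginal distributions of public combination screens, or
multi-label therapeutic ontologies. Passing the recovery tests shows the
machinery is correct and calibrated on its stated generative model — not
that any fingerprint will reach a particular score on real screening data.

## Numerical conventions

* Cross-entropy probabilities are clamped to [1e-12, 1 − 1e-12]; VAE
  log-variances to [−15, 15].
* `CKA` values are clamped into [0, 1] only after computation, and the raw
  HSIC terms are always retained.
* Fisher-z intervals refuse |r| = 1 folds (infinite z) and report them as
  degenerate with a warning.
* All RNG flows through explicit seeds (`set.seed` per training run,
  per-repeat derived seeds in cross-validation), so every pipeline is
  reproducible end to end.
* The unbiased-HSIC minimum sample size (m ≥ 4) and the centering minimum
  (m ≥ 2) raise informative errors rather than producing silent NaNs.

## Interfaces

This is an analysis package: the exported functions (`standardizeSmiles`,
`ruleFingerprintMatrix`, `trainGAE`/`trainVAE`, `cka`/`pairwiseCKA`,
`benchmarkFingerprints`, `scoreTable`, the `gen*` generators) and the
experiment drivers `runVS1()`/`runVS2()`/`runVS3()` with `fpbenchConfig()`
are the interface; no shell entry point is shipped. `readSmiFile()` and
plain CSV tables cover file-based input, and `fpbenchConfig(smilesFile=,
tuplesFile=)` runs the experiments on user data instead of the simulators.

## Known limitations

* No 3D (conformer-based) fingerprints without a user-supplied backend;
  no pre-trained graph-contrastive or transformer fingerprints.
* The chirality "other" featurizer slot is defensive: standard tetrahedral
  SMILES can only express unspecified/@/@@, so the fourth slot is exercised
  by unit tests rather than by generated molecules.
* Tautomer and protonation-state normalization beyond fragment stripping
  is out of scope.
* The GAE/VAE trainers are plain-R implementations intended for desk-scale
  corpora (hundreds to thousands of molecules), not for training on
  millions of compounds.
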