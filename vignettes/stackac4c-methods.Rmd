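---
title: "Methods: stacked ensemble prediction of ac4C sites"
author: "stackac4c"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stacked ensemble prediction of ac4C sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stackac4c)
```

## The problem

N4-acetylcytidine (ac4C) is an acetylation of cytidine that modulates mRNA
translation. Experimental mapping (acRIP-seq) is slow and expensive, so
sequence-based classifiers are used to triage candidate cytidines: given a
fixed-length nucleotide window centred on a candidate site, predict whether
it carries the modification. The public benchmarks for this task come as
positives/negatives FASTA pairs of fixed-length windows (hundreds of
positives against up to ten times as many negatives), which is exactly the
input shape this package consumes.

`stackac4c` implements the full predictor: three sequence encoders fused
into a 196-dimensional feature vector, cluster-centroid undersampling for
the imbalanced case, a two-layer stacking ensemble, and an imbalance-aware
evaluation suite with stratified cross-validation.

## Sequence handling

All computation is on the RNA alphabet `{A, C, G, U}`; `T` is mapped to `U`
on input so DNA- and RNA-convention FASTA files behave identically. Any
other character is rejected with its position — benchmark windows contain no
ambiguity codes, and imputing one would silently distort composition
features. Labels are attached per file (a positives file and a negatives
file), mirroring how the benchmarks are distributed.

## Feature encoders

### k-mer composition (48-D)

For word size $k$, the encoder counts overlapping $k$-mers and divides by
the number of windows, $L - k + 1$, so each block sums to exactly 1
regardless of window length. The package's canonical 48-D block is a
composite: the 16 dinucleotide frequencies plus the 32
reverse-complement-collapsed trinucleotide classes ($16 + 32 = 48$). The
composite's internal structure is this package's documented reconstruction
of a 48-dimensional k-mer block — no single $k$ gives $4^k = 48$ — and any
other composition can be configured through `encoder_config()`.

### PseKNC (84-D)

Pseudo K-tuple nucleotide composition augments the $4^k$ tuple frequencies
($k = 3$ by default) with $\lambda$ sequence-order correlation factors.
Tier $j$ is

$$\theta_j = \frac{1}{L-j-1} \sum_{i=1}^{L-j-1}
  \Theta(R_iR_{i+1},\; R_{i+j}R_{i+j+1}), \qquad
\Theta(d_1, d_2) = \frac{1}{6} \sum_{v=1}^{6}
  \left[P_v(d_1) - P_v(d_2)\right]^2,$$

where $P_v$ are six dinucleotide physicochemical indices. The final vector
shares one denominator across both parts,

$$d_\mu = \frac{f_\mu}{\sum_i f_i + w\sum_j \theta_j} \;(\mu \le 4^k),
\qquad
d_{4^k+j} = \frac{w\,\theta_j}{\sum_i f_i + w\sum_j \theta_j},$$

so the whole $(4^k + \lambda)$-vector sums to 1. Defaults are $k = 3$,
$\lambda = 20$ (the unique standard setting giving the 84-D vector) and
$w = 0.1$, the conventional weight for this family of encoders; all three
are configuration keys. $\lambda$ must satisfy $\lambda < L - 1$ or the
deepest tier has no position pairs to average.

The six indices — rise, roll, shift, slide, tilt, twist — are the published
RNA base-pair-step helical parameters, shipped as a plain-text table
(`inst/extdata/rna_dinucleotide_physchem.tsv`) and user-replaceable. Each
index is standardized to mean 0 / SD 1 over the 16 dinucleotides before the
correlation is computed, the established convention for pseudo-composition
encoders: it removes the units so no index dominates the squared
difference.

### PseEIIP (64-D)

Each trinucleotide $xyz$ scores its normalized overlapping frequency
weighted by the summed electron-ion interaction pseudopotentials of its
bases, $\mathrm{EIIP}_x + \mathrm{EIIP}_y + \mathrm{EIIP}_z$, with A =
0.1260, C = 0.1340, G = 0.806, and U carrying the published thymine value
0.1335 (the potentials are tabulated for DNA bases; uracil inherits
thymine's). Trinucleotides absent from the window score exactly zero.

### Fusion

The fused vector is the fixed-order concatenation (k-mer composite, PseKNC,
PseEIIP) = 48 + 84 + 64 = 196 dimensions, with names prefixed by encoder
tag so part boundaries remain recoverable. A canonical feature order is what
makes serialized models portable: prediction refuses schema mismatches by
name rather than silently mis-aligning columns.

## Class imbalance: cluster-centroid undersampling

The realistic benchmark is roughly 1:10 positive:negative; trained naively,
the ensemble buys accuracy by sacrificing sensitivity. The package balances
the *training* split by K-means clustering the majority class in feature
space with $K$ equal to the desired majority count (default: the minority
count) and replacing the majority rows by the $K$ cluster centroids.
Minority rows pass through bit-identical and in order.

Two consequences are worth stating loudly. First, centroids are synthetic
feature-space points with no underlying sequence, so per-sequence analyses
(motif inspection, window reporting) must run before resampling. Second, the
test split is left untouched by default — resampling a test set biases
evaluation — though `resample_test` exists for comparability with protocols
that reduce both splits.

K-means details: Lloyd's algorithm seeded by k-means++ (written in-package;
base R provides Lloyd but not the seeding), 10 restarts keeping the lowest
within-cluster sum of squares, 300 iterations, all deterministic given the
seed.

## The stacking ensemble

Layer 1 holds five heterogeneous base classifiers: L2 logistic regression
(LR), an RBF-kernel SVM with Platt-scaled probabilities, k-nearest
neighbours (KNN), a random forest (RF), and a single-hidden-layer
perceptron (MLP). Layer 2 is an L2-regularized logistic meta-learner whose
inputs are one positive-class probability per base classifier — probability
outputs only, never decision values, which is why the SVM is fit
probability-calibrated.

Meta-features are built **out of fold**: the training rows are split into
`oof_folds` stratified folds (default 5), and each row is scored by base
models trained on the complementary folds only. Training the meta-learner on
in-fold predictions would let it learn the base models' training error — the
classic stacking leak. After the meta-fit the base models are refit on all
training rows for deployment. The test suite re-derives every out-of-fold
block from scratch and asserts bitwise agreement, so the no-leakage property
is checked, not assumed.

Folds are stratified everywhere; with 1:10 imbalance, unstratified folds
can easily lose an entire class. Fold assignment is drawn by index given the
seed, so permuting training rows permutes fold membership: determinism is
guaranteed for a fixed (data order, seed) pair, which is the reproducibility
contract the run manifest records.

### Hyperparameters and their translation

The tuned hyperparameter values are stored verbatim in `base_spec()`
objects. Fitting maps them onto the backing R implementations:

| Spec field | Backing implementation |
|---|---|
| LR `C`, meta `meta_c` | `glmnet` ridge logistic, penalty $\lambda = 1/(nC)$, fit along a short decreasing $\lambda$ path for convergence |
| SVM `C=1.6134`, `tol=0.078`, rbf | `e1071::svm`, `probability = TRUE` |
| SVM `degree=0.2651` | recorded; inert under an RBF kernel |
| KNN `n_neighbors=20` | `class::knn` vote fractions |
| KNN `leaf_size=17` | recorded; a search-tree detail with no statistical effect |
| RF `max_depth=10`, `min_samples_split=10`, `min_samples_leaf=1` | `ranger` probability forest: `max.depth`, `min.node.size`, `min.bucket`; 100 trees |
| MLP `hidden_layer_sizes=(11)`, `alpha=1e-05` | `nnet` size 11, weight decay |
| MLP `batch_size`, `momentum`, `beta_1/2`, `epsilon`, `learning_rate_init` | recorded; Adam-specific, inert under nnet's BFGS optimizer |

The MLP's `max_iter = 8532` counts stochastic-gradient epochs; under BFGS
(a second-order batch optimizer that converges in far fewer steps) the
package caps the translated iteration limit at 200 with a tightened
relative tolerance, a deliberate optimizer-appropriate rendering rather
than a faithful unit conversion.

Six base-classifier combinations are enumerated for comparison
(`enumerate_combinations()`): the five leave-one-out quadruples and the full
ensemble.

### Repeated cycles

`repeated_fit_average()` trains the ensemble over independent cycles — each
cycle re-draws fold partitions, fit seeds and (optionally) the
undersampling — and reports per-cycle validation (pooled stratified CV) and
independent-test metrics plus their arithmetic mean and SD. Whether repeated
runs should vary the resampling draw as well as the folds is genuinely open;
the package varies both, keyed off the cycle index, because both are part of
the training pipeline's randomness.

## Evaluation

`compute_metrics()` reports Sn = TP/(TP+FN), Sp = TN/(TN+FP),
Acc = (TP+TN)/N, the Matthews correlation with its standard square-root
denominator, trapezoidal ROC-AUC (via pROC), and PR-AUC by step integration
of the precision-recall curve (preferred under imbalance; no installed
package provides it, so it is written here with tie-aware threshold
grouping). The classification threshold defaults to 0.5 and is a flag.
A zero Mcc denominator is reported as 0 with a warning and an explicit
degenerate-case flag; one-class inputs yield `NA` for Mcc and both AUCs
rather than a silent 0.

Cross-validation reports the **pooled** out-of-fold metrics as the headline
number (every sample scored once by a model that never saw it) and keeps
per-fold reports, because repeated-run protocols average whole-run metrics.
ROC-AUC is checked in the tests against an independent Mann–Whitney
pair-counting oracle to 1e-12.

`independent_test()` fingerprints training rows and warns when a test row
coincides with one — it cannot prove disjointness, but it catches the common
accident.

## The synthetic benchmark generator

Real benchmark data must be downloaded, so every stage is exercised against
a seeded generator (`simulate_dataset()`) that emulates the benchmarks'
*structure*: fixed-length windows (default 201 nt), configurable class
ratio (balanced to ~1:10), and a positive-class signal modelled as excess C
probability at codon-position-1 sites — reflecting the observation that
acetylated transcripts are enriched for cytidine-containing codons — with a
single continuous effect-size knob (`c_enrichment`), uniform background
composition by default, and byte-level reproducibility from the seed.

What the generator does **not** emulate: positional motif structure beyond
the codon phase, the redundancy structure of real transcriptomes (no
CD-HIT-like near-duplicates), window-level GC heterogeneity, or any
dependence between neighbouring positions. Passing the synthetic
signal-recovery checks therefore demonstrates that the pipeline's plumbing
and learning machinery work — not that the predictor attains any particular
accuracy on real benchmark downloads.

## Problem sizes and numerical conventions

The test-suite and acceptance-script sizes are the package's chosen
desk-scale study conditions: oracle equivalence on 20 random length-30
windows (tolerance 1e-10), normalization sums over 100 random windows
(1e-12), undersampling on a 330-window 1:10 set, and end-to-end signal
recovery on 500 positives / 500 negatives of length 201 with enrichment 0.4
(strong) and 0.0 (null), evaluated by pooled 5-fold cross-validation of the
full five-classifier stack with 3 out-of-fold folds. Under those conditions
the strong-signal pooled ROC-AUC exceeds 0.9 by a wide margin and the
null-signal ROC-AUC stays within 0.5 ± 0.08.

Other conventions: k-mer frequencies use the $L - k + 1$ overlapping-window
denominator (so blocks sum to 1); the physicochemical table is standardized
with the sample SD; feature tables are written at 6 significant digits and
round-trip at that precision; all seeds are plain integers recorded in the
run manifest.

## Limitations

* The 48-D k-mer block composition is a reconstruction; models trained with
  a different composition are schema-incompatible by design.
* Centroid rows produced by undersampling have no sequence counterpart.
* The hyperparameter translation table above is faithful where a counterpart
  exists and explicit where it does not; identical numbers on other
  implementations should not be expected.
* Synthetic results bound plumbing correctness, not real-data accuracy; for
  real evaluation, download a benchmark FASTA pair and run the pipeline on
  it.
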