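---
title: "Models and methods in tcrlearn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in tcrlearn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

tcrlearn models T-cell receptor (TCR) repertoires from the two pieces of
information that commercial TCR-Seq platforms report: the CDR3 amino-acid
sequence of each chain and the V/D/J gene segments that formed it. This
vignette describes the models the package implements, the assumptions they
make, the tunable parameters that matter, and the choices we made where the
design was genuinely open. Nothing stated here as an empirical result goes
beyond what the package's test suite and `scripts/acceptance.R` themselves
compute.

## Data model and curation

A clone is one row of a clone table: sample id, CDR3 amino-acid sequence(s),
gene labels, a summed read/UMI count, and an optional label. Curation
(`parseCloneTable()`) applies three filters before any analysis: sequences
using letters outside the 20-residue alphabet (`*`, `X`, `O`, ...) are
removed; sequences longer than `maxLength` (default 40 residues — no
plausible CDR3 is longer) are removed; unproductive rows are removed, where
"unproductive" means a mapped status column says so, or — in the absence of
such a column — the row has no CDR3 at all. Vendors disagree on how
unproductive rearrangements are marked, which is why the status column is an
explicit mapping rather than a guess. Clones identical in amino-acid
sequence, gene labels and sample are merged with counts summed; the
aggregation key deliberately includes the gene labels, because two CDR3s
with identical amino acids but different V genes are different receptors in
this representation.

Encoding (`encodeTCRs()`) maps residues to integers 1..20 in alphabetical
one-letter order, right-pads to `maxLength` with a distinguished 21st pad
code, and indicator-codes each gene slot against a `GeneVocabulary` with a
reserved "absent" index. The pad code has its own (trainable) embedding row
rather than reusing a residue index, so the network can learn a null
representation for padding. Encoding and decoding are exact inverses; an
unseen gene label under a fixed vocabulary is an error, never a silent
remap.

## The TCR featurization block

All models share one featurization block. Per chain: a trainable embedding
of dimension 64 over the 21 symbols, followed by three convolutional layers
with (kernel, stride, maps) = (5, 1, 32), (3, 3, 64), (3, 3, 128) and
rectifier nonlinearities. Per gene slot: a trainable embedding of dimension
48. All blocks are concatenated into the joint feature vector.

Choices the architecture description leaves open, and what we chose:

* **Padding scheme.** SAME-style zero padding with ceil-division output
  lengths (40 → 14 → 5 at `maxLength` 40), so motifs at sequence edges stay
  learnable.
* **Pooling.** The VAE flattens the final convolutional layer; the
  supervised and repertoire models apply global max pooling over positions.
  Positions beyond a clone's true (propagated) length are masked to -Inf
  before the max so padding can never win; this is what makes the pooled
  value of a kernel invariant to where its best-matching subsequence sits.
  The argmax position of every kernel is recorded per clone; motif
  extraction reads it back.
* **Nonlinearity.** Rectifier, the era's default; the source description is
  silent.
* **Gene embeddings.** One table per gene slot, not shared: V and J
  vocabularies are disjoint categorical spaces.
* **Chains.** Each enabled chain has its own convolutional stack; the
  amino-acid embedding is shared.

The networks are implemented directly on matrix algebra: im2col convolution
with BLAS matrix products, hand-derived backpropagation verified against
central finite differences in the test suite, and Adam optimization. Dense
products run in single precision (the field's standard for network
training); a double-precision path exists and is what the gradient-check
tests use. Training at the problem sizes in this vignette runs in seconds
to a few minutes on one CPU core.

## Variational autoencoder

The unsupervised model is a VAE over the flattened featurization:
encoder bridge (one fully connected layer, width 256) to a diagonal
Gaussian `N(mu(x), sigma(x))` in a latent space of default dimension 64
(configurable; the comparisons in our tests use 16), decoder bridge (one
fully connected layer, width 256) to per-position 20-way softmax logits per
chain and a categorical softmax per gene slot.

The loss is the sum of (i) reconstruction cross-entropy, summed over true
(unpadded) positions and gene slots — pad-region predictions never enter
the loss — and (ii) the closed-form KL divergence to a unit Gaussian,
`0.5 * sum(mu^2 + sigma^2 - 1 - log sigma^2)`, with weight 1 and no
annealing. Training uses reparameterized sampling (`z = mu + sigma * eps`);
feature extraction is deterministic and returns `mu`, because downstream
clustering must not depend on sampling noise. Convergence is declared when
the relative improvement of the epoch loss stays below `tol` (default 1e-4)
for `patience` (default 10) consecutive epochs.

The decoder uses fully connected bridges rather than a deconvolutional
stack; at CDR3 lengths (≤ 40 positions) a dense map from a 256-wide hidden
layer is adequate and keeps the decoder symmetric with the encoder bridge.
The decoder exists for training only — the package does not generate novel
sequences from the prior.

Ablations mirror the three variants compared in the benchmarking harness: a
sequence-only VAE has no gene parameters at all, a gene-only VAE has no
sequence parameters, so neither can receive gradients from inputs it does
not use.

## TCR distances and benchmarking

Four distance featurizations produce symmetric, zero-diagonal matrices:

* **Latent Euclidean** on VAE features.
* **Hamming** on the right-padded integer representation, pad positions
  included, so sequences of different lengths are comparable ("CASS" vs
  "CAS" differ at one position). Reported as a raw count; as a constant
  multiple of the padded-length fraction it is rank-equivalent for KNN and
  clustering.
* **k-mer**: Euclidean distance between k-mer count vectors (default k = 3).
* **Global alignment**: with unit match score and no mismatch or gap
  penalty the optimal global alignment score `s(a,b)` equals the longest
  common subsequence, and `d = 1 - 2 s(a,b) / (s(a,a) + s(b,b))` is
  symmetric, zero on the diagonal and bounded in [0, 1]. The normalization
  is a reconstruction of the cited identity-scoring construction and is
  isolated in one function for easy replacement; it is not asserted to be
  a metric (the tests check the triangle inequality only for Hamming and
  k-mer).

The evaluation harness applies average-linkage agglomerative clustering
(linkage is unstated in the source description; average linkage behaves
uniformly across all four distance types) over a grid of cluster counts,
scoring each solution with the variance ratio criterion and adjusted mutual
information against ground-truth labels. VRC needs coordinates, so for
precomputed distances it is computed in a classical MDS embedding of
dimension `min(n - 1, 50)` — a reconstruction, isolated and swappable. AMI
uses the hypergeometric expected-MI correction with arithmetic-mean
normalization. KNN classification uses stratified five-fold
cross-validation on the precomputed distances; a test clone's class scores
are neighbor-vote fractions, ties at the k-boundary break by clone index
for determinism, and AUC is the midrank rank-statistic (so constant scores
give exactly 0.5).

## Supervised sequence models

The classifier sends the global-max features directly to a softmax layer
(cross-entropy); the regression variant sends them to a single node (mean
squared error), with an optional `log1p` target transform. Training uses
Adam at learning rate 0.001, a 75% training split with the remaining 25%
divided evenly into validation (early stopping, patience 10 evaluations,
best weights restored) and test; the validation/test subdivision is a
choice — the source description only fixes the 75/25 split. Monte-Carlo
cross-validation re-draws the split per repetition from
repetition-indexed seeds; a clone's reported prediction is the mean over
repetitions in which it was held out, and clones never held out are
reported absent (`NA`), not zero. Downstream interpretation uses only these
held-out predictions.

## Repertoire classifier (multi-instance learning)

Each clone's feature vector passes through `nConcepts` (default 12) linear
heads, each ending in the adaptive inverse-square-root unit

`aisru(x) = L + (H - L)/2 * (1 + x / (a + (x^2)^b)^(1/(2b)))`,

with per-head trainable `a > 0` and `b >= 1` (positively reparameterized
through softplus) and `L = 0, H = 1`. As printed without the `+1` shift the
algebraic core maps onto `(-(H-L)/2, (H-L)/2)` — i.e. `(-0.5, 0.5)` under
`L = 0, H = 1` — which contradicts the intended (0, 1) assignment range;
the shifted form is therefore the default and the unshifted core is kept
behind `shifted = FALSE`. This is the single most consequential
reconstruction in the package. The activation is strictly increasing,
smooth, and its gradient decays only polynomially in `|x|`, which is the
stated motivation for preferring it to a sigmoid.

The per-repertoire proportion of a concept is the arithmetic mean of its
clones' assignments (a count-weighted mean is available by flag but off by
default: pooling is over sequences). Proportions feed a softmax
classification layer; the loss is cross-entropy over repertoire labels.

Training a bag-level model on a handful of wells invites memorization of
individual training-well clones instead of discovery of the shared
sequence concept. Three standard regularizers counter this, all exposed in
`repertoireConfig()`: per-step subsampling of each well (default 64 clones
per well per step, making bags stochastic), dropout on the joint feature
vector (default 0.5), and decoupled weight decay on weight matrices and
embeddings (default 1e-3). Inference always uses full wells and is
deterministic. Because only a few wells are available, convergence is
monitored on the training loss (relative-improvement criterion); held-out
wells — not a validation split — assess generalization.

The screening procedure trains `nReps` models (default 100; the desk-scale
runs in this package's tests use 20), each re-initialized from a
repetition-indexed seed, holding out one replicate well per condition.
Held-out predictions accumulate into the screening AUC (cognate vs control
wells) and the Delta Prediction (mean held-out cognate prediction minus
mean control prediction); a response is flagged significant at AUC > 0.90,
a configurable cutoff reproduced as stated rather than calibrated as a
test. Per-sequence inference scores each clone as a singleton repertoire.
Pairwise variant comparison runs the screen in both orientations for every
condition pair and reports `1 - mean(Delta)`; the diagonal is 1 by
convention.

For desk-scale screening schedules (tens of epochs rather than the long
schedules a GPU affords) we recommend — and the package's own evaluation
uses — a learning rate of 0.01 for this model; the package-wide default
remains 0.001. All attention heads share the featurization trunk.

## Interpretation

Motif extraction ranks clones by held-out predicted probability per class,
fits the per-class predictions on pooled kernel activations by multinomial
linear regression (activations are centered; a rank-deficient design falls
back to ridge with a warning; the regression fits probabilities, with a
logit option), and for the top-associated kernel harvests the
receptive-field window at each top clone's argmax position. Layer 1
(width-5 windows) is the default — deeper layers have receptive fields of
7 and 13 positions computed from the stride schedule and are available via
the `layer` argument. Windows clipped at boundaries are padded with `-`
and flagged; harvested windows yield a position-frequency matrix (columns
sum to 1) and consensus, exportable in MEME minimal format.

Residue sensitivity substitutes every position of every present chain with
all 19 alternatives (exhaustive, deterministic; `19 x length` deltas per
chain) and records signed prediction deltas. Per position, magnitude is
the mean absolute delta and direction the arithmetic mean signed delta
(a majority-vote option exists). The Residue Sensitivity Logo encodes
magnitude as glyph size and direction as color — red where most
substitutions lower the prediction, blue where they raise it. The
sensitivity-vs-annotation AUC ranks per-position magnitudes against any
binary position annotation (e.g. contact residues from a structure);
annotations are an input — the package does not parse structures.

## Synthetic study conditions

The generator (`simulationConfig()`, `simulateSequenceDataset()`,
`simulateWellExperiment()`) emulates the statistical structure of
antigen-sorted and culture-well TCR data: background CDR3s are uniform
random strings over the 20 letters (configurable to empirical
frequencies), lengths uniform on 10–20, framed by the canonical C...F
junction termini (off by flag); class motifs (default: random 4-mers drawn
from the seed, the short-motif regime typical of antigen-specific CDR3
cores) are implanted as contiguous substrings at uniform admissible
offsets in a `motifRate` fraction of clones; gene usage is class-tilted
(bias 0.5 by default); counts are geometric (success probability 0.3), a
heavy-tailed clone-size surrogate.

The well experiment models splitting one well-mixed culture across wells:
all wells share a common background clone pool (equal-split aliquots:
every pool clone appears in every well, with per-well abundance noise in
the counts), and cognate wells carry signal clones at `motifRate` — fresh
sequences per well sharing only the motif, as replicate antigen-specific
responses share specificity but not clonotypes. Presence/absence dropout
of rare clones across wells is deliberately not modeled; with it, well
identity becomes partially learnable from background composition and
screening at desk-scale training budgets degrades. Real culture data
carry additional structure the generator omits — clonal expansion shared
across replicate wells, nonuniform residue usage, pairing errors in
single-cell data — so passing tests demonstrate correct and sensitive
machinery on the stated conditions, not performance claims about any real
dataset.

Problem sizes used throughout the package's own evaluation: 300 clones
(3 classes) for the VAE/supervised fixtures; 12 wells of 200 clones and 20
Monte-Carlo repetitions for screening; these sizes run the whole
evaluation in minutes on one CPU core while leaving the learning problems
non-trivial.

## Numerical and degenerate-input policy

Probabilities are floored at 1e-12 before logs; log-variances are clamped
to [-15, 15]; a non-finite training loss aborts with a diagnostic rather
than continuing silently. Empty wells, empty datasets after curation,
single-class labels, sequences shorter than k (k-mer), empty sequences
(alignment), and cluster counts at or above n are all explicit errors or
skips with warnings, as the respective function documents. Determinism:
every stochastic routine draws from named substreams of one master seed;
training is reproducible to the extent the BLAS allows.

## Known limitations

* Training on one CPU core bounds the problem sizes; the networks are
  small by deep-learning standards, and very large repertoires would need
  minibatched streaming beyond what the package provides.
* The alignment-distance normalization and the MDS embedding for VRC are
  reconstructions of under-specified steps and are isolated for
  replacement.
* The repertoire screen's AUC threshold (0.90) is a reproduced cutoff, not
  a calibrated hypothesis test.
* CDR1/CDR2 and HLA context are not modeled; annotations such as contact
  residues are inputs, never derived.
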