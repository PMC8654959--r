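---
title: "Methods: multi-headed convolutional classification of anticancer peptides"
author: "ACPcnn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-headed convolutional classification of anticancer peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ACPcnn)
```

## The problem and the model

Anticancer peptides (ACPs) are short peptides — roughly 10 to 50 residues —
with cytotoxic activity against tumour cells; distinguishing them from
inactive peptides (often antimicrobial peptides without anticancer activity)
from primary sequence alone is a standard binary sequence-classification
problem with small training sets.

ACPcnn classifies a peptide from its *k* N-terminal residues (default
`k = 15`; shorter peptides are post-padded with all-zero rows).  Each
truncated peptide is encoded into up to three fixed-shape numeric matrices:

* **BPF** — a `k x 20` one-hot *binary profile* in the fixed residue order
  A, R, N, D, C, Q, E, G, H, I, L, K, M, F, P, S, T, W, Y, V;
* **PHYSCHEM** — a `k x 31` 0/1 matrix of physicochemical group
  memberships: 10 bits for overlapping residue classes and 21 bits for
  seven attributes (polarity, normalized Van der Waals volume,
  hydrophobicity, secondary structure, solvent accessibility, charge,
  polarizability), each splitting the 20 residues into 3 disjoint groups,
  so every residue's 21-bit segment carries exactly 7 ones;
* **BLO62** — a `k x 20` matrix whose rows are the raw integer BLOSUM62
  substitution scores of each residue, summarising its evolutionary
  exchangeability.

Each active representation feeds its own *convolutional group*: two stacked
1-D convolutions along the sequence axis (representation columns are the
input channels), stride 1, "valid" extent, ReLU activations, and **no
pooling** — with only `k = 15` input rows there is nothing to downsample,
and pooling would discard residue-order information.  The branch outputs
are flattened, concatenated, passed through one or two dense ReLU
recombination layers (this is where information from different
representations first mixes), and a final two-unit softmax produces the
class probabilities.  Dropout follows every convolutional and dense layer;
an L2 penalty `lambda * sum(w^2)` is attached to all weight matrices.  The
whole network — all branches plus the recombination layers — is trained
jointly by minimising cross-entropy with Adam.

With the default branch (length-4 kernels feeding length-3 kernels, stride
1) one unit of the second convolutional layer sees
`1 + (4 - 1) + (3 - 1) = 6` consecutive residues: an *effective receptive
field* of 6, enough to cover short sequence motifs inside a 15-residue
window (`effectiveReceptiveField(c(4, 3))`).  The seven possible subsets of
the three representations are labelled C1–C7 (`combinationSets()`); each
subset instantiates one branch per member.

## Tunable parameters

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `k` | 15 rows | N-terminal truncation depth; `"max"` encodes full sequences |
| `conv1` | 10 filters, kernel 4, dropout 0.8 | first conv layer of each branch (acp740 profile) |
| `conv2` | 8 filters, kernel 3, dropout 0.7 | second conv layer |
| `denseLayers` | 8 units, dropout 0.7 | recombination layer(s) |
| `l2Lambda` | 1e-3 | weight of the squared-norm penalty |
| `learningRate` | 1e-3 | Adam step size |
| `batchSize` | 32 | minibatch size |
| `maxEpochs` | 200 | epoch cap |
| `patience` | 20 epochs | early stopping on validation loss |
| `minEpochs` | 50 | early-stopping warm-up (see below) |
| `validationFraction` | 0.1 | stratified internal validation split |
| `seed` | 1 | drives initialisation, splits, shuffling, dropout |

Two architecture presets are shipped (`presetConfig()`): **acp740** as in
the table above, and **acp500** (16 filters of length 3, dropout 0.7; then
8 of length 3, dropout 0.5; dense 16/0.6 then 8/0.5).  Dropout rates at or
above 0.5 and the L2 penalty are what make these very small networks
trainable on datasets of a few hundred peptides without memorising them.
The optimiser settings (`learningRate`, `batchSize`, `maxEpochs`,
`patience`, `l2Lambda`) are package defaults chosen as ordinary values for
Adam on problems of this size; all are exposed in `mhcnnConfig()`.

Note one wrinkle worth knowing: the receptive-field arithmetic of 6 holds
for the acp740 profile (kernels 4 then 3); the acp500 profile stacks two
length-3 kernels and therefore spans 5 residues.  Both profiles are
implemented exactly as configured; neither is adjusted to force a common
receptive field.

### The early-stopping warm-up

With dropout rates of 0.7–0.8 the optimisation typically spends its first
few dozen epochs on a loss plateau before the motif signal is picked up.
A bare patience counter on validation loss can fire inside that plateau,
freezing a chance-level model for some seeds.  Early stopping is therefore
only *armed* after `minEpochs` (default 50, capped at `maxEpochs`); the
patience rule and best-weight restoration are unchanged otherwise.  This is
the standard "start-from-epoch" guard used by mainstream training loops.

## Encodings: numerical choices

* **Padding value.** PAD rows are all-zero in every representation — the
  neutral input for a convolution (and for the one-hot and bit encodings, a
  vector no real residue can produce).
* **BLOSUM62 scaling.** Substitution scores are used as published
  (integers, half-bit units); no standardisation is applied.  The shipped
  file is the standard NCBI-format BLOSUM62; any NCBI-format matrix can be
  substituted, and rows/columns outside the canonical alphabet (B, Z, X,
  `*`) are dropped on load.  With an identity matrix the BLO62 encoder
  reduces exactly to the one-hot encoder, which the tests exploit as an
  oracle.
* **Column order.** Every matrix is indexed by the same fixed residue
  order, so one-hot columns and substitution-matrix columns align.
* **Property table provenance.** The 10 overlapping classes and the 7x3
  partitions are *content*, not structure: the shipped table uses a
  Taylor-style physicochemical Venn classification (hydrophobic, polar,
  small, tiny, aliphatic, aromatic, charged, positive, negative,
  hydroxylic) and the canonical CTD attribute tables of Dubchak et al.
  The loader enforces only the structural invariants — exactly 10 overlap
  groups; exactly 7 attributes whose 3 groups are disjoint and exhaustive —
  so users can swap in any table they prefer
  (`loadPropertyTable(path)`).
* **Nonstandard residues.** B, J, O, U, Z and friends are a hard error by
  default; `onInvalid = "skip"` drops the record with a warning, and
  `onInvalid = "zero"` keeps it with the residue masked as `X`, which every
  encoder maps to an all-zero row (the same treatment as padding).
  Stop characters (`*`) are stripped with a warning; sequences are
  uppercased and trimmed.

## Training and evaluation: numerical choices

* **Initialisation.** Glorot-uniform weights, zero biases, drawn from the
  config seed; building a model twice with the same config is bitwise
  reproducible, as is training (shuffling, dropout masks and splits all
  come from the same seeded RNG stream).
* **Decision rule.** Label 1 iff the positive-class probability strictly
  exceeds 0.5; an exact tie yields the negative class (conservative
  positive calls).
* **Metric conventions.** Accuracy, sensitivity, specificity and precision
  are on the percent scale; MCC is reported as 0 whenever any marginal of
  its denominator is zero (the no-correlation reading of an undefined
  ratio).  An empty denominator for the percent metrics yields `NaN`
  rather than a silent 0.
* **ROC/AUC.** The curve is a threshold sweep over the distinct scores;
  AUC is the trapezoid integral, which with half-credit for ties equals the
  pairwise-concordance (rank) statistic — the equality is asserted in the
  tests to 1e-9.
* **Folds.** `stratifiedKFold()` shuffles each class with the seed and
  deals records round-robin, continuing the deal across classes; per-class
  counts *and* total fold sizes then differ by at most 1 (e.g. a 376/364
  dataset gives five folds of exactly 148 with 75–76 positives).
* **Cross-validated ROC.** The per-dataset curve pools the out-of-fold
  scores of all folds (per-fold AUCs are also kept).  Pooling was chosen
  over curve averaging because it yields a single well-defined empirical
  curve from exactly one score per record.
* **CV seeds.** Fold `f` trains with `seed + f`, so a CV run is one
  deterministic function of (data, config, seed).

## The synthetic generator

`generateSynthetic()` draws peptides of 10–50 residues from a uniform
background over the 20 residues; positives carry a configurable N-terminal
motif (default `KWKLFK`, length 6 — matching the default receptive field)
implanted at a uniform offset within `motifWindow` (default 5) of the
N-terminus with probability `signalProb`.  This emulates the one property
of real ACP data that the architecture is designed to exploit — a
short, position-localised N-terminal sequence signal — and supports a
clean null (`signalProb = 0`, or label shuffling).

What it does **not** emulate: realistic residue composition (real peptides
are far from uniform), correlated or degenerate motifs, class-dependent
length distributions, homology between records, label noise, or the
physicochemical coherence of real ACPs (amphipathicity, net positive
charge).  Passing the recovery tests therefore shows that the
implementation can learn a plantable signal through each encoding — it is
a correctness check on the machinery, not evidence about performance on
real peptides.  The test suite uses generator sizes of 10–600 records and
short CV configurations so the whole suite runs in about a minute on one
CPU; these sizes are a package choice that keeps the checks cheap while
leaving the learning tests non-trivial.

## Known limitations

* The trainer is a compact, single-threaded implementation intended for
  peptide-scale inputs (hundreds to thousands of records, `k` up to ~100);
  it is not a general deep-learning framework and has no GPU path.
* Full-sequence mode (`k = "max"`) widens the flattened layer
  considerably; with small datasets the parameter count then grows faster
  than the information available, and the short receptive field covers
  proportionally less of the sequence.
* Class weighting is not implemented; the intended datasets are
  near-balanced.
* The shipped property table is one defensible choice of group content;
  results of the PHYSCHEM branch depend on it, which is why it is an
  editable file rather than hard-coded.

## Reproducing a run

Every CLI run writes `provenance.yaml` (package version, mode, seed,
options, resolved model configuration); re-running the same subcommand with
that configuration and seed reproduces the artifacts exactly.  The same
holds in code: `crossValidate()` twice with the same dataset, config and
seed produces identical report tables.
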