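---
title: "Learning Watson-Crick complementarity: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning Watson-Crick complementarity: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. Nothing here states an empirical number that the
test suite or `scripts/acceptance.R` does not itself recompute.

## The classification task

Over the RNA alphabet $\Sigma = \{A, C, G, U\}$, two strands $s,
\bar{s} \in \Sigma^L$ (both written 5'→3') are *fully complementary* when
every position pairs by the Watson-Crick rule:
$s_i = c(\bar{s}_{L+1-i})$ for all $i$, with $c(A) = U$, $c(C) = G$ and
their inverses. The classifier sees a hairpin-shaped token sequence

$$x = \mathrm{PAD}^{\,10-L}\; s\; a\; \bar{s}\; \mathrm{PAD}^{\,10-L},$$

where $a$ is a random apical loop (default a tetraloop, lengths 3–7
supported), and must output a *positivity score* $y \in (0,1)$, thresholded
at $\theta$ to decide whether the pair is fully complementary. The target is
deliberately elementary: if a model family struggles here, there is little
hope it grasps base pairing inside a full secondary-structure predictor.
This framing also fixes the package's two ground-truth devices: the *exact
complement* $s^*$ (the unique positive partner of $s$) and the brute-force
*oracle classifier*, which re-checks the pairing predicate character by
character and is implemented independently of the generator's integer
arithmetic, so each validates the other.

## The synthetic-data generator

`partition_sequence_space()` splits all $4^L$ stems into disjoint train and
test pools, so within-length evaluation never re-uses a training stem.
`generate_dataset()` then draws stems from a pool with replacement, makes a
fraction $\alpha$ of examples positive ($\bar{s} = s^*$), draws negative
partners uniformly over the $4^L - 1$ stems other than $s^*$, and — for
training data only — flips each observed label independently with
probability $\mu$. Test sets always have exactly equal counts of true
positives and negatives and zero flipped labels.

What the generator emulates is the *statistical* structure of a
training/testing split: controllable quality ($\mu$), balance ($\alpha$),
size ($N$) and structural dissimilarity (stem length, via training on one
length and testing on another). What it does not emulate is any
thermodynamic or structural realism — loops are uniform random nucleotides,
there is no G·U wobble or non-canonical pairing, and negatives are uniform
rather than energetically plausible near-misses. Passing tests therefore
demonstrate properties of learning algorithms under controlled dissimilarity,
not performance on biological data.

Choices the task description leaves open, fixed here once:

* **Partition split.** A shuffled exact split (default half/half) rather
  than a per-stem Bernoulli draw, so pool sizes are deterministic given the
  seed.
* **Stem sampling.** With replacement; duplicated stems within a training
  set are permitted (they still differ in loop and/or negative partner).
  Only train/test overlap is forbidden.
* **Test sets.** Within-length runs sample a balanced 10,000-example test
  set from the held-out pool (configurable); length-extrapolation runs use
  the exhaustive balanced set over all $4^{L_{test}}$ stems — one positive
  and one negative per stem, $2 \cdot 4^8 = 131{,}072$ examples at length 8.
* **Token codes.** PAD = 0, A = 1, C = 2, G = 3, U = 4, fixed for
  reproducibility; positions are 1-based in all documentation.

## Architectures and the capacity ledger

All four families are three-layer networks over a learned 4-dimensional
nucleotide embedding whose PAD row is frozen at zero, sharing the head
`linear(U)–batchnorm–ReLU–dropout–linear(1)–sigmoid`:

* **MLP** — flattened embedding (96 inputs), then
  `linear(H)–batchnorm–ReLU–dropout`.
* **Att** — sinusoidal positional encodings added to the embeddings, a
  kernel-1 convolution projecting 4 → H channels, then the residual block
  `batchnorm(h1 + dropout(self_attention(h1)))` with H heads.
* **LSTM** — a one-layer bidirectional LSTM, H hidden units per direction,
  no internal dropout.
* **CNN** — an outer concatenation turning the 24×4 embedded matrix into a
  24×24×8 tensor (cell $(i,j)$ concatenates the encodings at positions $i$
  and $j$, so every potential pairing is spatially explicit), a 3×3
  convolution (stride 1, padding 1) with H feature maps, then
  batchnorm–ReLU–dropout.

Capacity is read from `capacity_table()`, a fixed ledger of $(H, U)$ pairs
indexed by $\log_{10} C$ for six levels between about $10^{2.7}$ and
$10^{5.5}$ parameters. The tests verify that the realised parameter count of
every one of the 24 (family, level) cells lies within 0.25 of its nominal
order of magnitude.

Three wiring decisions were genuinely open and were settled by the ledger
itself:

* **Aggregation before the head.** Per-position features are *flattened*
  (not pooled) for Att, LSTM and CNN; flattening is what reproduces the
  ledger's parameter-count magnitudes. The CNN is the loosest fit
  (about $10^{4.32}$ at the $10^{4.15}$ level) — pooling variants would
  shrink it, but flattening keeps all four families structurally parallel.
* **Attention head dimension.** The attention layer's capacity is set by the
  number of heads H acting on an H-dimensional projection, which forces
  one-dimensional heads. This literal reading is implemented as such (the
  score scale $1/\sqrt{d_{head}}$ is 1), with a dedicated kernel in
  `src/mhsa.cpp`.
* **Batch normalisation placement.** Over the feature dimension after each
  linear layer; for the per-position layers (Att residual, CNN maps) the
  statistics pool over batch × positions, i.e. standard per-channel
  normalisation.

## Training protocol

`train_model()` minimises the α-weighted binary cross-entropy

$$\ell(y, t) = -\left[\tfrac{1-\alpha}{\alpha}\, t \log y +
  (1-t) \log(1-y)\right]$$

with Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$),
learning rate $10^{-3}$, weight decay $10^{-3}$, shuffled batches of 256,
and $8 \times 10^4 / N$ epochs so that the number of gradient updates is
essentially constant (320 for every grid size $N \ge 250$) no matter how
large the training set is. With $\alpha = 1/2$ the loss is the standard
binary cross-entropy; at $\alpha = 1/3$ each positive example counts double,
exactly balancing a 2:1 negative excess.

Numerical and protocol choices:

* **α is recomputed from observed labels** (after any mislabelling), the
  literal reading of the loss's definition of the positive fraction; under
  heavy flipping the construction-time α and the observed α differ slightly.
* **Epoch rounding**: half-up with a floor of one epoch.
* **Loss clamping**: scores are clamped to $[10^{-7}, 1 - 10^{-7}]$ inside
  the loss only, so the loss trace is finite even for saturated sigmoids.
* **Weight decay** is added to the gradient (L2-style, coupled with Adam's
  moment estimates), the classic Adam `weight_decay` semantics.
* **Ties** $y = \theta$ count as predicted negative, following the
  accuracy definition's "$\le \theta$" branch.
* **No early stopping, no schedule, no validation split** — the protocol is
  fixed so that capacity and data, not tuning, drive the results.
* **Determinism**: a single integer seed per repetition derives the
  partition, dataset, initialisation and shuffling/dropout seeds, so every
  simulation is exactly reproducible; small batches are never reduced below
  two examples (batch statistics need at least two).
* **Initialisation**: uniform fan-in scaling for linear/convolution layers,
  $U(-1/\sqrt{H}, 1/\sqrt{H})$ for LSTM parameters, Xavier-uniform for the
  attention projections, standard-normal embeddings with the PAD row frozen
  at zero. The zero PAD row matters: padding positions contribute nothing to
  any layer, which is precisely what makes length-wise extrapolation
  interesting (weights attached to never-seen positions receive no data
  gradient, only decay).

The training engine itself — a small reverse-mode tape over matrix
operations, with the attention score/softmax loop in C++ — is part of the
package and is verified against central finite differences for all four
architectures in the test suite.

## Evaluation and experiments

`accuracy()` implements thresholded accuracy at $\theta = 1/2$;
`run_simulation()` chains partition → datasets → model → training →
evaluation from one repetition seed; `run_simulations()` averages over
seeds $\mathrm{base}, \mathrm{base}+1, \dots$; `run_experiment()` sweeps
grids and aggregates. The probe set (`probe_examples()`) fixes three
length-8 diagnostics on the self-complementary stem `ACGUACGU`: the true
positive, and two negatives whose mismatches are produced by substituting
the correct base with its own complement (which can never pair) at pair
positions 6–8 and 2–4 respectively — the former is the sequence
`ACGUACGUGAAAACGUAGCA`. Both variants use the same complement-substitution
rule, so the two probes differ only in where along the stem the mismatches
sit relative to the padding.

## Problem sizes

The package's headline checks (the acceptance test file and
`scripts/acceptance.R`) run at desk scale: 10 repetitions per condition
instead of 50, and 5 random-forest seeds. Ten-seed means are noisier than
fifty-seed means — the acceptance tolerances are sized accordingly
(e.g. ±3 percentage points on the length-5 extrapolation mean, ±15 on the
deliberately high-variance attention cell). The exhaustive length-8 test
set is always used in extrapolation cells; within-length cells use the
10,000-example sampled test set.

## Known limitations

* Uniform negatives make the task easier than discriminating near-complements;
  an `α`-style control for partial complementarity (a regression on the
  fraction of paired positions) is out of scope.
* No attention masking of PAD positions: padded positions enter the
  attention softmax with zero embeddings plus positional encodings.
* The KNN baseline uses uniform voting (its reference implementation's
  default); with 35 neighbours on noisy data its training accuracy cannot
  reach 100%, so no such behaviour is asserted.
* Classifier comparisons are accuracy-only at a fixed threshold; no
  ROC/AUC or calibration analysis.
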