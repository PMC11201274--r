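---
title: "Graph-based seizure detection: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based seizure detection: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific content of `seizgraph`: the model
and its assumptions, the parameters that matter, what the synthetic
generator does and does not emulate, and the numerical and design choices
made where more than one reasonable option existed.

## The problem and the model

Seizure detection is cast as *transductive binary node classification*.
Every 30 s EEG window is a node; an undirected edge joins two nodes when
the Euclidean distance between their min–max-scaled feature vectors is
strictly below 0.2. All windows — training, validation, test, and any
synthetic oversampled rows — are present in one graph during training;
labels outside the training partition are never used by the loss. At
inference time unseen windows are attached to the frozen training graph by
the same distance rule, which provably reproduces a full rebuild on the
concatenated feature matrix (the equivalence is asserted in the test
suite).

The shared backbone is a six-layer graph convolution with the
symmetric-normalized propagation rule

$$H^{(l+1)} = \mathrm{ReLU}\!\left(\tilde D^{-1/2}(A+I)\tilde D^{-1/2}
H^{(l)} W^{(l)}\right),$$

with widths $d \to 256 \to 256 \to 256 \to 256 \to 256 \to 16$. Self-loops
are added before normalization even though the bare propagation rule is
often printed without them: without self-loops an isolated node has an
undefined $D^{-1/2}$ and a zero row annihilates its features. Two heads
share this backbone:

* **GCN-LSTM** — a single-layer LSTM (input 16, hidden 256) consumes the
  node sequence ordered by window start time, and a linear map
  ($256 \times 2$ weights + 2 biases = 514 trainable scalars) emits logits
  at every step. Emitting per-step logits (rather than only at the final
  hidden state) is required for per-window classification; a
  `final_state_only` switch reproduces the sequence-level reading exactly.
  Synthetic oversampled nodes have no acquisition time and are appended
  after the real sequence.
* **GCN-BRF** — the GCN is first trained with a temporary linear softmax
  map on the 16-d embeddings; the map is then discarded and a balanced
  random forest (100 trees, Gini CART, $\sqrt d$ feature subsampling,
  each tree on an equal-count bootstrap of both classes) is fitted on the
  training-node embeddings. The forest's ictal-vote fraction is the score
  used for ROC analysis. There is no gradient flow from the forest into
  the GCN; the two stages are deliberately separate.

## Features

Each channel of each window contributes 19 features in the default
`compact19` profile:

* 15 statistical descriptors with fixed conventions: population variance,
  skewness as the standardized third central moment, *excess* kurtosis,
  coefficient of variation as population SD over mean (reported as 0 with
  a warning when the mean is exactly zero — the alternative, ±Inf, would
  poison downstream scaling), line length $\sum_i |x_i - x_{i-1}|$,
  Teager non-linear energy $\mathrm{mean}(x_i^2 - x_{i-1}x_{i+1})$, and
  Shannon entropy of a 100-bin amplitude histogram over the window's own
  range. Binning over the window's own range makes the entropy invariant
  to amplitude scaling, which is asserted as a property test.
* Daubechies db8 (8 vanishing moments) wavelet summaries: mean of the
  level-5 approximation coefficients and the SD of all detail coefficients
  pooled across levels. Five levels were chosen because at 256 Hz the
  detail subbands then align with the clinical bands (64–128 … 4–8 Hz)
  and the approximation covers 0–4 Hz. Periodization boundary handling
  makes the transform orthogonal, so subband energies sum to the signal
  energy (relative error below 1e−8 whenever the window length is
  divisible by $2^{\text{levels}}$; a 30 s window at 256 Hz is).
* Welch spectral summaries (256-sample Hann segments, 50 % overlap,
  per-segment constant detrend): total non-DC power and spectral entropy.
  The `extended` profile adds per-level detail SDs, per-subband energies
  and the five clinical band powers for exploration.

Cross-channel aggregation takes the mean and the population variance of
each feature across channels, producing $19 \times 2 = 38$ columns. This
makes the representation independent of channel count and ordering (a
property test permutes channels), at the cost of discarding topographic
information — a deliberate trade-off that keeps recordings with different
montages comparable.

The exact composition of the 38-feature set is a package convention: it is
the smallest set consistent with the three feature families and the
printed column count, and it is the default rather than the only option.

## Graph construction choices

* Distances are computed on min–max-scaled features (scaler fitted on
  training rows only). Raw feature magnitudes span orders of magnitude
  (energy vs. skewness), so an absolute threshold is only meaningful after
  scaling.
* The edge rule is strictly `<` 0.2; a pair at exactly the threshold is
  not connected (tie behaviour is pinned by a test).
* Edges are unweighted and the graph is simple (no self-pairs,
  deduplicated).
* Node indices are 1-based inside R; exported edge lists are written
  0-based, which is the convention of most graph tooling.

## Training recipe

Adam with learning rate 0.001 and L2 weight decay 5e−4; cross-entropy
loss; 60/20/20 shuffled split; at most 50 epochs in minibatches of 64
training-node indices. Because the graph is a single connected object,
"batch" means a subset of node indices contributing to the loss of one
update step while propagation always spans the full graph — at desk scale
a full-graph forward pass is cheap, and this is the only reading under
which a batch size is meaningful for one graph. Early stopping monitors
validation loss with patience 10 and restores the best-validation weights;
no learning-rate schedule is used. Class-weighted loss is off by default
since imbalance is handled by oversampling.

Leakage control is structural: the scaler is fitted on training rows only,
the oversamplers accept only the training partition, and a test perturbs
the evaluation rows and asserts that neither the scaler state nor the
resampler output changes. The split-before-oversampling order is enforced
because the alternative (oversampling before splitting) lets interpolated
copies of evaluation windows leak into training.

Weight initialization is Glorot-uniform, seeded; LSTM forget-gate biases
start at 1 (standard practice to keep early memory open). Gate order is
(input, forget, candidate, output). Per-layer GCN biases are on by
default and switchable, since published parameter counts for this
architecture family are not self-consistent enough to pin the choice.

## Oversampling

* **SMOTE**: synthetic minority row $s = p + \lambda(q-p)$ with $q$ one of
  the $k=5$ nearest minority neighbours of $p$ and
  $\lambda \sim U(0,1)$; the minority count is brought exactly to
  `round(target_ratio × majority)`.
* **KNNOR**: three density-aware refinements — donors whose distance to
  their $k$-th minority neighbour exceeds the population median are
  excluded (sparse outliers make unsafe donors); $\lambda$ is capped at
  0.5 so candidates stay near their donor; each candidate must survive a
  majority-vote check among its $k$ nearest neighbours in the
  augmented-so-far population. Generation retries up to 20 attempts per
  requested point and returns a partial augmentation with a warning if the
  cap is hit.

The samplers are implemented natively so their geometric postconditions
(segment membership, convex-hull containment, neighbourhood votes) are
directly testable; $k$, the target ratio, $\lambda_{max}$ and the safety
quantile are configuration knobs with the stated defaults, as no canonical
values exist for them.

## The synthetic generator

`simulate_recording()` produces 256 Hz multichannel signals: per channel,
one random-frequency random-phase sinusoid per clinical band (delta 20,
theta 10, alpha 15, beta 5 µV by default) plus 1/f noise (10 µV RMS,
spectrally shaped white noise). Inside each annotated interval it adds a
shared spike-and-wave train — per 1/3 s cycle, a narrow Gaussian spike
(σ = 15 ms) followed by an opposite-sign half-sine slow wave — at
100 µV × gain (default gain 2) with per-channel gain jitter in
[0.8, 1.2], plus 20–60 Hz burst noise at 15 µV RMS. These defaults were
fixed once to give a clearly ictal ~3 Hz signature over a plausible
background, and they define the package's synthetic study conditions: 20
recordings of 10 minutes with one 60 s seizure each (≈15 % ictal windows).

What the generator does *not* emulate: physiological spatial topography,
seizure evolution (onset build-up, post-ictal suppression), artifacts
(EMG, EOG, electrode pops), inter-patient variability, or non-stationary
background. Consequently, passing end-to-end tests demonstrates that the
pipeline is implemented correctly and can learn a genuinely separable
ictal signature — it does not demonstrate clinical-grade performance on
real EEG, where published results at this accuracy level require the
corresponding clinical corpora.

EDF export uses a fixed ±1000 µV physical range at 16-bit resolution with
one-second data records; seizure annotations travel in a plain-text
tab-separated sidecar in the style of CHB-MIT summary files.

## Numerical notes and degenerate inputs

* The pairwise Euclidean distance is used for edges; a printed variant
  that differences consecutive entries of a single vector is inconsistent
  with comparing two windows and is not implemented.
* Periodized DWT requires even lengths at every level; windows are
  multiples of $2^{5}$ samples at the default rates. Constant windows
  yield zero entropy by convention (single occupied histogram bin).
* Welch segments are constant-detrended so a DC offset contributes no
  band power; the spectral entropy of white noise then approaches
  $\log_2$(number of non-DC bins), which is tested within 5 %.
* ROC/AUC use all unique scores as thresholds with trapezoidal
  integration, which equals the exhaustive pairwise-concordance statistic
  including tie handling (asserted against an independent oracle).
* Cohen's kappa is $(p_o - p_e)/(1 - p_e)$ with the usual marginal
  expectation; a single-class truth vector makes AUC undefined and it is
  reported missing with a warning rather than silently dropped.
* Whole-recording inference averages window scores over every second a
  window covers; trailing seconds not covered by any complete window are
  reported as `NA` rather than extrapolated.

## Problem sizes

The test suite and the acceptance script run the full pipeline on the
synthetic study conditions above (560 windows, ≈800 graph nodes after
oversampling); unit and property tests use windows of a few hundred to a
few thousand samples and graphs up to 300 nodes against independent
brute-force oracles. These sizes were chosen as the smallest at which
every claimed property is exercised at realistic imbalance and
separability.

## Known limitations

* The LSTM consumes nodes in window-start-time order; for concatenated
  multi-recording datasets this is the recording order, and alternatives
  (e.g. graph-traversal order) are not explored.
* The distance threshold 0.2 is treated as a constant of the method; its
  sensitivity is not tuned or searched.
* No artifact rejection, montage re-referencing or filtering is applied
  before feature extraction.
* The balanced forest consumes frozen embeddings; joint optimization of
  both stages is out of scope by design.
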