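---
title: "Adaptive spatiotemporal graph convolution for fNIRS classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive spatiotemporal graph convolution for fNIRS classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asgcn)
```

## The problem

Functional near-infrared spectroscopy (fNIRS) records cortical hemodynamics
through source-detector channel pairs. In the cohort design this package
targets, 44 channels cover bilateral frontal and temporal cortices: left
frontal lobe channels 1-10, left temporal 11-22, right frontal 23-32, right
temporal 33-44. Each channel reports three concentration-change attributes —
oxygenated (HbO2), deoxygenated (Hb) and total hemoglobin (HbT, identically
HbO2 + Hb) — sampled every 0.07 s for about eight minutes (roughly 6857
samples), giving one m x 132 matrix per subject. The task is binary
diagnosis: children with autism spectrum disorder (ASD, label 1) versus
typically developing children (TD, label 0).

Two obstacles shape the method. Cohorts are small (tens of subjects), so a
subject cannot be the training unit; and the discriminative signal is partly
*spatial* — which channels co-fluctuate — which channel-by-channel
classifiers ignore.

## Sliding-window reconstruction

Each recording is cut into short overlapping windows of `w` samples advanced
by `s` samples (defaults `w = 30`, `s = 10`; 2.1 s and 0.7 s at the 0.07-s
sampling interval). A recording of `m` samples yields

    N_i = (m - w) / s,   rounded to the nearest integer,

windows, window `k` (0-based) covering rows `[k*s, k*s + w)`. Two
conventions deserve comment. First, the count formula omits the `+ 1` of the
fully-inclusive convention; we follow the printed formula, so the final
window starting at `m - w` is dropped when the fraction rounds down.
Second, the rounding rule is fixed by arithmetic: for `m = 6857`,
`(6857 - 30)/10 = 682.7`, and only nearest-integer rounding (683
windows/subject, 19124 for a 28-subject training set) reproduces the
documented tensor sizes; floor is available behind
`window_config(rounding = "floor")`. Windows inherit their subject's label,
and one attribute and one channel region are selected before windowing, so a
dataset is a 4-D tensor `(N, w, c, 1)`.

Splits are *by subject*, never by window — overlapping windows from one
subject are highly correlated, and letting them straddle train and test
would leak. `make_splits()` shuffles each class separately (seeded) and
allocates 6:2:2: the train count is the floor of the train share, the
remainder goes to validation first (ceiling of its share), then test. For
25 ASD + 22 TD this yields train 28 (15/13), validation 10 (5/5), test 9
(5/4).

```{r splits}
cohort <- simulate_cohort(cohort_config(n_asd = 25, n_td = 22, m = 400,
                                        seed = 1))
make_splits(cohort, seed = 1)
```

## The classifier

Channels are nodes of a graph with no pre-defined adjacency. Three pieces
combine into the network fitted by `asgcn()`.

**Adaptive graph learning (AGL).** A learnable node embedding
`E` (N x d, default d = 7, d << N) induces the adjacency

    A = row_softmax(ReLU(E E^T)),

computed with per-row max subtraction. Rows sum to one, so `A` acts as an
attention-like averaging operator; the propagation matrix is `I_N + A`
(first-order Chebyshev form, no further degree normalization). Although
`E E^T` is symmetric, *row-wise* softmax of a symmetric matrix is generally
not; we keep the row-stochastic (possibly asymmetric) matrix for computation
and symmetrize as `(A + A^T)/2` only for connectivity reporting.

**Node-weight-adaptive learning (NWAL).** A shared graph-convolution weight
`W` for all nodes underfits heterogeneous channels, while a full per-node
tensor `N x C x F` overfits. The middle ground is a low-rank factorization:
a shared weight pool `W_pool` (d x C x F) is contracted with the same
embedding, `W_i = sum_k E[i,k] W_pool[k,,]`, and likewise for biases. One
layer computes `Z_i = ((I + A) X)_i W_i + b_i`. When every row of `E` is
identical this is exactly the shared-weight convolution — the degenerate
limit the test suite exploits as an oracle.

**Graph-convolutional GRU (GCGRU).** Temporal structure is captured by a
GRU whose gate transformations are NWAL graph convolutions over the
concatenated `[h_prev, X_t]` features:

    z_t = sigmoid(G_z([h_{t-1}, X_t]))
    r_t = sigmoid(G_r([h_{t-1}, X_t]))
    hhat_t = tanh(G_h([r_t * h_{t-1}, X_t]))
    h_t = (1 - z_t) * h_{t-1} + z_t * hhat_t

`h_t` is an entrywise convex combination of `h_{t-1}` and a tanh output, so
hidden states initialized in [-1, 1] stay there. All gates in all layers
share the single embedding `E` with the adjacency ("unified node
embedding").

The encoder stacks two GCGRU layers (layer 2 consumes layer 1's hidden
sequence); the decoder applies a 1x1 convolution collapsing the hidden axis
to one value per node, then a fully connected layer over nodes to a single
logit, then a sigmoid.

### Design choices where the architecture was open

* *Readout.* Only the final time step's hidden state feeds the decoder —
  the standard GRU-classifier convention; consuming all steps is a
  reasonable alternative we did not take.
* *Decoder head.* A single logit with sigmoid pairs naturally with the
  binary cross-entropy loss; a 2-logit softmax head would be equivalent
  with one parameter more.
* *Gate concatenation order* is `[h_prev, X_t]`.
* *Layer sharing.* The two encoder layers have separate gate pools but one
  shared `E`.
* *Initialization.* Pools are drawn uniform with a Glorot-style bound on
  the **effective** per-node weight: since `W_i` contracts d pool slices
  with embedding entries of variance 1/d, the pool bound is
  `sqrt(6/(C_in + C_out))` and embedding rows are scaled to unit variance.
  (A plain fan-in bound on the pool itself makes the effective weights
  smaller by a factor of about sqrt(d * C) and measurably stalls early
  training.) Bias pools start at zero; the seed fixes everything.
* *Input normalization* (per-window z-scoring) exists behind
  `normalize_input` but defaults to off; the generator already produces
  unit-scale signals, and nothing in the data pipeline resamples or
  filters.

## Training and evaluation

`asgcn()` minimizes binary cross-entropy with Adam (lr 0.001 by default, no
learning-rate or weight decay), batch size 64, at most 100 epochs, and early
stopping: training stops once the validation loss has not improved for
`patience = 15` consecutive epochs, and the best-epoch parameters are
restored. A non-finite loss aborts with the last good parameters and a
warning.

Window-level metrics follow the standard confusion-count definitions;
accuracy is `(TP + TN) / total` — the fraction of windows diagnosed
correctly. Sensitivity `TP/(TP+FN)` and specificity `TN/(TN+FP)` matter
clinically because they separate the ability to detect ASD from the ability
to clear TD. Undefined ratios surface as `NaN` with a warning rather than a
silent 0. A subject-level majority vote over each subject's windows is
reported by `asgcn_evaluate()` as a labelled extra; all headline numbers are
window-level. `roc_auc()` offers a full threshold sweep and a three-point
mode (max, mid-range, min thresholds); both close the curve with (0,0) and
(1,1) and integrate by trapezoid. The two modes coincide when their
threshold sets induce the same classifications (always for two or fewer
distinct scores) but not in general — the mid-range threshold need not
match the middle *value*.

`run_experiment_grid()` re-runs the pipeline varying exactly one axis —
window length (20/30/50 samples = 1.4/2.1/3.5 s), attribute (HbO2 vs Hb;
HbT is excluded as the exact sum of the other two), or cortical region (six
lobe/hemisphere subsets) — with splits, seed and all other settings fixed.

## Learned connectivity and edge ablation

The trained adjacency is itself a result: `extract_adjacency()` exports the
(symmetrized) matrix, `top_edges()` mines the strongest off-diagonal pairs
(diagonal excluded as autocorrelation; symmetric duplicates merged; ties
broken lexicographically). `strong_pairs_44()` ships the eleven
frontotemporal pairs this workflow flags on the 44-channel montage, as the
default input to the ablation.

`edge_ablation()` quantifies an edge's contribution by *retraining* with
that pair's adjacency entries clamped to exact zeros at every forward pass
(both symmetric entries, after the softmax, no renormalization — deleting an
edge should not silently rescale the others). Test metrics are recorded
every epoch after a 5-epoch burn-in, giving a distribution per condition;
all conditions share one seed. A cheaper `mode = "inference"` masks only at
evaluation time, which answers a different question (how much does a
trained model rely on the edge) and is kept behind the flag for that
reason. The burn-in length and the one-run-per-condition default are
conventions: early-epoch metrics are dominated by initialization noise, and
a `--seeds`-style generalization is available simply by calling the
function at several seeds.

## The synthetic cohort generator

No public fNIRS cohort accompanies this design, so `simulate_cohort()`
stands in. Per channel, HbO2 is a sum of three sinusoids with random
frequencies in `osc_band_hz` and random phases; class structure is planted
by one-shot linear mixing along a known edge set
(`x_i <- x_i + coupling * sum_j x_j`, then rescaling to unit variance)
before Gaussian noise; Hb is `-0.3` times HbO2 plus independent noise
(hemodynamic anticorrelation, cosmetic); HbT is the exact sum. Each subject
draws from a private RNG stream derived from the cohort seed, so cohorts
are pure functions of their configuration.

What the generator emulates: the matrix layout, the HbT identity,
slow oscillatory structure (default band 0.01-0.1 Hz, spontaneous
hemodynamic timescales), and — crucially — class-specific spatial
correlation, the one property every downstream test relies on. What it does
not emulate: hemodynamic response shapes, optode geometry, motion and
systemic artifacts, non-stationarity, or any physiological asymmetry
between groups. Passing tests therefore demonstrate that the pipeline,
model and training recover *planted spatial structure*; they say nothing
about clinical performance on real recordings.

Two fixture conventions used by the test and acceptance cohorts: the
oscillation band is raised to about 0.15-0.8 Hz so that a single 2.1-s
window contains visible oscillation (with the default band a 30-sample
window is nearly linear and within-window coupling is much harder to read),
and problem sizes are kept deliberately small — 10-channel cohorts of 20
subjects with 1400 samples each for the classification property, 4-channel
cohorts for the ablation fixture, and one 28-subject full-size cohort for
the window-count conservation check. With coupling 0.6 and noise SD 0.2, a
logistic-regression oracle on within-window correlations reaches about 0.96
validation accuracy on the 10-channel fixture, so the 0.9 expectation
placed on the network leaves honest headroom rather than sitting at the
ceiling.

The ablation fixture deserves one honest caveat. Because softmax rows are
strictly positive, every unmasked node still mixes all channels; deleting
the (1,2) entries removes the *direct* route to the planted cross-channel
feature but not the two-hop routes through other nodes, so a masked model
eventually relearns the feature. The handicap is therefore largest
mid-training, and the fixture measures it there: 15 epochs with a 5-epoch
burn-in, a strongly coupled single edge (0.85) so the unmasked baseline
converges well inside that budget, and the same seed for both conditions
to pair the comparison.

## Numerical notes and limitations

* Softmax rows subtract their max before exponentiation; the BCE loss is
  computed from logits in the `log1p(exp(-|x|))` form.
* Gradients are fully analytic (backpropagation through the decoder, both
  GCGRU layers through time, the weight pools, and the softmax/ReLU
  adjacency into the shared embedding) and are verified against central
  finite differences to better than 1e-3 relative error in the suite.
* `ReLU(E E^T)` has a kink at 0; entries exactly at 0 take the
  zero subgradient. With continuous random initialization this is a
  measure-zero event.
* Training the full 44-channel, 64-hidden configuration on a 19124-window
  tensor is a multi-hour pure-R computation; the package is honest about
  being a reference implementation. Its testable claims are correctness
  (oracles, closed forms, gradients) and recoverability of planted
  structure at small scale, not wall-clock parity with GPU frameworks.
* Cohort exchange uses per-subject CSV plus a manifest (and RDS for
  prepared tensors/checkpoints); no HDF5 container is provided.
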