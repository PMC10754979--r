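---
title: "Time-spatial parallel networks for motor-imagery EEG: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-spatial parallel networks for motor-imagery EEG: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The decoding problem

Motor imagery modulates sensorimotor EEG rhythms: imagining a movement
changes band-limited power (classically in the mu/alpha and beta bands)
over contralateral motor cortex. A six-class upper-limb decoder must tell
apart movements (hand open/close, forearm supination/pronation, elbow
flexion/extension) whose signatures differ subtly in which electrodes and
which frequency bands are modulated. This package implements TSPNet, a
convolutional architecture that factorizes this problem into three stages:

1. **Temporal feature extraction (TDFE).** A `1 x 7` stem convolution along
   time, followed by three stages of *parallel residual blocks* with
   temporal kernels `1 x 1` and `1 x 3` and widths increasing 64, 128, 256
   (each branch: convolution, additive skip, batch normalization,
   rectification; branch outputs are summed). Only the time axis is
   convolved, so electrodes are processed independently and the stage is
   equivariant to electrode permutations.
2. **Spatial feature extraction (SDFE).** One parallel residual block with
   *spatial* kernels `1 x 1`, `3 x 1`, `5 x 1` across the electrode axis at
   width 512, then max-pooling (size 2, stride 2) over electrodes. A
   variant replaces pooling with stride-2 spatial convolution.
3. **Time-spatial parallel feature extraction (TSPFE).** For each feature
   channel, the `H x W` slice `X` (spatial x temporal) is scored by a
   similarity matrix

   `Q = (P X)' D (P X)`

   where `P` is constrained orthogonal and `D` is a learnable diagonal.
   `Q` is normalized two ways — a column-wise softmax `Qc` and a
   column-wise softmax of the transpose `Qr` — and each re-projects the
   slice (`Fc = X Qc`, `Fr = X Qr`). A rectified gating mechanism
   (`F * relu(w_f . F + b_f)`, with `w_f . F` a `1 x 1` convolution across
   feature channels) reweights each branch, and the two gated branches are
   concatenated, doubling the channel count. Global average pooling, an
   affine map and a softmax produce class probabilities; training minimizes
   weighted multiclass cross-entropy (weights default to 1; the protocol
   keeps classes balanced).

The orthogonality of `P` is structural, not penalized: `P = expm(A - A')`,
the matrix exponential of the skew-symmetric part of an unconstrained
generator `A`. The exponential of a skew-symmetric matrix is exactly
orthogonal for every value of `A`, so `P'P = I` holds after any number of
optimizer steps. The backward pass uses the adjoint identity for the
Fréchet derivative of the matrix exponential (evaluated via the standard
2x2 block-matrix construction).

## Interpretation choices in the architecture

Several aspects are under-determined by the defining equations; the
package's choices, and why:

* **Batch-norm placement.** The block equations carry no explicit
  normalization; it appears only in the original figure annotations. We
  normalize *after* the skip addition: `z_b = BN(conv_b(x) + skip(x))`,
  `out = sum_b relu(z_b)`. With normalization before the addition the raw
  skip is re-added once per parallel branch, so activation magnitude
  grows geometrically with depth — orders of magnitude above the input
  scale within a few blocks. That regime saturates the similarity softmax
  of the head, makes the rectified gate's pre-activation scale-dominated
  (a small negative drift of `w_f` closes the gate at every position; a
  closed ReLU gate receives no gradient and cannot reopen), and in our
  development runs collapsed training to uniform predictions. Normalizing
  after the addition keeps every stage O(1) and training is stable.
* **Skip form.** `skip(x)` is the identity when input and output widths
  match and a learned `1 x 1` projection otherwise. The non-residual
  ablation removes exactly this term.
* **Branch fusion** is elementwise summation, as the equations are
  written, never concatenation (except for the final `[Fc, Fr]`
  concatenation, which the defining equation states explicitly).
* **Shared head parameters.** One `(P, D)` pair and one gate per branch are
  shared across all feature channels; per-channel parameter sets would add
  `512 * H^2` parameters with no textual support.
* **Softmax axis.** Columns, for both `Qc` and `softmax(Q')`. Transposing
  `Q` exactly swaps the two normalizations (a tested identity).
* **Gate activation** is ReLU, as stated, although sigmoid is conventional
  for gates. ReLU gates can die: if the pre-activation is negative at every
  position the gate output and its gradient are both zero, permanently. We
  therefore initialize the gate weights at exactly zero with bias one: the
  gate starts open and independent of the feature scale.
* **Similarity diagonal init.** `D` is initialized at `0.1`; `Q` entries
  scale like `H * |X|^2 * d`, and this keeps the softmax responsive at the
  start of training rather than saturated.
* **Temporal decimation.** The similarity matrices are `W x W` per feature
  channel. At the native `W = 1500` they would be computationally
  indefensible; the package average-pools the temporal axis (window =
  stride = smallest integer bringing `W` under `w_max`, default 64) before
  the head. This is declared plumbing, not part of the published
  equations.
* **Global average pooling** averages over both spatial and temporal axes,
  one value per feature channel.
* **Argmax ties** break toward the lowest class index.

## Training and evaluation protocol

The reference optimizer profile is ADAM with initial learning rate 0.001,
gradient decay 0.9, squared-gradient decay 0.999, global gradient-norm
clipping at 1, mini-batches of 64, up to 1000 epochs, and a step-decay
schedule multiplying the rate by 0.1 every 500 epochs (so the rate is
1e-4 from epoch 500). Evaluation uses stratified 70/30 splits per class,
re-drawn independently for each of 10 shuffles; the per-shuffle test
accuracies are reported as mean plus/minus sample standard deviation.
Pairwise method comparisons use the two-sided pooled-variance t-test at
significance 0.05 on the per-shuffle accuracy samples. Training is
per-subject by default; the chance level for six balanced classes is
16.67%. The ablation matrix evaluates six variants — no temporal stage,
non-residual temporal blocks, no spatial stage, stride-2 spatial
reduction, no time-spatial head, and the full network — under identical
partition seeds, so comparisons are paired.

Inputs are z-scored per trial and channel along time before training.
This removes absolute-amplitude cues, so classification rests on spectral
shape and cross-channel structure — the conservative reading of what a
band-power modulation should leave behind.

## The synthetic data generator

Real six-class recordings exist but are large and non-redistributable, so
every stage here is exercised on synthetic motor-imagery EEG with
controllable class structure:

* **Background**: independent `1/f^a` noise per channel (spectrally shaped
  white Gaussian noise, unit variance, default slope `a = 1`).
* **Class signal**: a band-limited random-phase process (white noise
  band-limited by a zero-phase frequency-domain mask) added on the class's
  target electrodes only, scaled by `effect_size` in background-SD units.
  A pure-tone mode substitutes a fixed-frequency sinusoid at the band
  centre for visualization sanity checks.
* **Signatures**: the default table assigns the six classes the six
  distinct (electrode, band) pairs from {C3, C4} x {theta 3-7, alpha 7-13,
  beta 13-30 Hz} — alpha (mu) and beta are the classic ERD/ERS bands over
  motor cortex, and the 16-site CytonDaisy layout carries C3 and C4 there.
  Delta is deliberately not used: at any sampling rate, delta periods span
  many times the `1 x 7` stem kernel, and band-power in that range is
  poorly resolvable by the architecture's temporal receptive field.
* **Optional 50 Hz line noise** is off by default (the emulated recordings
  are notch-filtered at acquisition).
* Identical configurations (including the seed) generate bit-identical
  epoch sets; labels are exactly balanced by construction.

What the generator does *not* emulate: volume-conduction correlations
between channels, non-stationarity within trials, eye/muscle artifacts,
inter-subject variability, or realistic ERD time courses (the modulation
spans the whole epoch). Passing tests on this data demonstrates that the
implementation can discover electrode-and-band structure end to end; it
does not certify real-data accuracy.

## Desk-scale study conditions

The published protocol (16 channels x 1500 samples, widths 64/128/256 +
512, 1000 epochs, 10 shuffles, 10 subjects) is far beyond a single CPU
core. The package therefore defines a *desk* condition used by its test
suite and acceptance script, chosen once:

* data: profile-I montage, 1 subject, 60 trials/class, 1.5 s epochs at
  32 Hz (48 samples), effect size 3 for the strongly discriminable regime
  and 0 for the null control;
* model: identical topology with widths 4/8/16 and SDFE width 16,
  `w_max = 32`;
* optimizer: the reference ADAM constants with mini-batch 32; 45 epochs
  for single-model checks (training loss has plateaued by then at effect
  size 3) and 15 epochs per run for the paired ablation comparison, where
  only the ordering of variants is asserted and the gap between the full
  network and its ablations is already wide.

Delta-band signatures were rejected during design: a delta cycle spans
many multiples of the `1 x 7` stem kernel at any sampling rate, so the
architecture's temporal receptive field resolves it poorly, and a desk
condition built on delta would measure the kernel span rather than the
method. Theta/alpha/beta avoid that confound.

At this scale one training run takes on the order of a minute, a full
paired ablation fits in minutes, and the learnability and visualization
properties below are stable across seeds. The `paper` profile retains the
full-scale constants verbatim for users with the compute (and the real
data) to run them.

## The band-occlusion visualization

To ask *which* frequencies and electrodes a trained classifier uses, the
visualization algorithm: (1) predicts on a held-out test set; (2) keeps
only correctly classified trials (accuracy on this subset is 1 by
construction); (3) band-passes those trials into delta 0.5-3, theta 3-7,
alpha 7-13 and beta 13-200 Hz versions (zero-phase 4th-order Butterworth,
applied forward-backward; a band edge at or above `0.45 fs` is clipped
there); (4) re-runs the feature extractor on each band-limited version up
to a tap point — the head output by default, the pre-head features for
before/after comparisons; (5) averages feature maps per class; and (6)
renders per-electrode importance as a scalp topography.

Two read-out details matter in practice. First, the band-filtered trials
enter the network *without* re-normalization: the trials were z-scored
before filtering, so each channel's post-filter variance is precisely the
fraction of that electrode's energy inside the band — the quantity the
read-out is meant to localize. Re-scoring after the filter would equalize
the channels and erase it (re-normalizing here breaks the localization
check that the test suite runs). Second, the
default electrode score contrasts each class's average map against the
across-class mean of the band: activation topography shared by all
classes — where the network allocates energy overall — cancels, leaving
the class-distinctive pattern that the per-category scalp maps are meant
to exhibit. Plain per-class averages remain available
(`contrast = FALSE`).

Step 6 must map the head's reduced spatial extent (electrode pairs, after
the spatial max-pooling) back to electrodes. We assign each pooled unit's
mean absolute activation to *both* of its member electrodes
(piecewise-constant upsampling) rather than interpolating linearly:
pooling genuinely discards within-pair resolution, and interpolation would
invent a gradient inside a pair that the data cannot support. Consequently
the topographic read-out cannot distinguish two electrodes that share a
pool pair; the built-in pure-tone signature table for visualization
checks therefore places its six classes on six electrodes in six distinct
pool pairs. This resolution limit is a property of the architecture's
spatial pooling, not of the rendering.

The name of the algorithm family notwithstanding, step 3 *retains* one
band at a time rather than removing it; the implementation follows the
printed steps exactly.

## Numerical choices and degenerate inputs

* Batch normalization: population statistics within a batch, running
  estimates (momentum 0.1) for evaluation; evaluation passes are
  bit-reproducible.
* Softmax: per-column max subtraction; cross-entropy clamps a zero
  probability at the true class to 1e-12 with a warning.
* Zero-variance channels z-score to all-zeros rather than NaN.
* Degenerate t-tests: zero pooled variance returns `t = 0, p = 1` for
  equal means and `p = 0` with a warning otherwise.
* Max-pool ties take the first (upper) electrode; an odd trailing
  electrode is dropped by pooling (spatial extent `floor(H/2)`) and
  inherits its neighbour pair's score in the topographic read-out.
* Gradient correctness is enforced by a finite-difference check in the
  test suite (relative error below 1e-4 on every parameter family, in
  every ablation variant; the implementation achieves ~1e-8).

## Known limitations

* The compiled kernels are single-threaded; large-profile training is
  possible but slow, and the published accuracies on the real recordings
  are out of scope here (they require the two datasets and GPU-scale
  training).
* The synthetic generator's independence across channels means spatial
  filters have an easier task than on real, volume-conducted EEG.
* The desk model's small widths bound the capacity; desk results
  demonstrate relative orderings (e.g. full network versus ablations), not
  absolute performance.
* Orthogonality of `P` is exact by construction, but `D` is unconstrained;
  nothing prevents a sign flip of a diagonal entry during training (the
  similarity form does not require positive-definiteness).
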