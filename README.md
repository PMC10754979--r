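# tspnet

Six-class upper-limb motor-imagery decoding from EEG with a time-spatial
parallel convolutional network, in R.

Motor imagery modulates band-limited EEG power over sensorimotor cortex.
Decoding *which* of six upper-limb movements (hand open/close, forearm
supination/pronation, elbow flexion/extension) a person imagines requires
features that are simultaneously frequency-selective and spatially
localized. `tspnet` implements the TSPNet architecture for this problem:

* **TDFE** — a `1 x 7` temporal stem plus three parallel residual stages
  (kernels `1 x 1`, `1 x 3`; widths 64/128/256) convolving only along
  time;
* **SDFE** — a three-branch parallel residual stage (kernels `1 x 1`,
  `3 x 1`, `5 x 1`; width 512) convolving only across electrodes,
  followed by spatial max-pooling;
* **TSPFE** — for each feature channel slice `X` (space x time), a
  similarity matrix `Q = (PX)' D (PX)` with `P` orthogonal by
  construction (`P = expm(A - A')`) and `D` a learnable diagonal; `Q` is
  softmax-normalized by columns and by rows, each normalization
  re-projects `X`, a rectified gate (`F * relu(w_f . F + b_f)`) reweights
  both branches, and their concatenation feeds a global-average-pooled
  softmax classifier trained with weighted cross-entropy.

The package also ships the full experimental protocol (stratified 70/30
splits repeated over shuffles, the reference ADAM profile with step-decay
learning rate and gradient clipping, pooled-variance t-tests, the
six-variant ablation matrix), a band-occlusion feature-visualization
algorithm with scalp-topography export on 10-20 montages, a synthetic
motor-imagery EEG generator (class-specific band-limited power on
motor-cortex electrodes over a 1/f background), and an HDF5 epoch
container with a command-line interface. The network forward/backward
passes are hand-written over compiled kernels (`src/`), so no deep
learning framework is required; gradients are verified against central
differences in the test suite.

## Worked example

Train a desk-scale network on synthetic data with a strong
class-discriminative effect, evaluate it, and ask which electrodes and
bands it uses:

```r
library(tspnet)

# 6 classes x 60 trials, 16 channels, 1.5 s at 32 Hz; class signatures are
# the six (electrode, band) pairs {C3, C4} x {theta, alpha, beta}
epochs <- generate_epoch_set(desk_synth_config(effect_size = 3, seed = 11))
split  <- stratified_split(epochs, train_fraction = 0.7, seed = 101)

model <- train_model(normalize_epochs(split$train),
                     desk_model_config(),
                     optimizer_profile("desk", max_epochs = 45),
                     seed = 101)
evaluate_model(model, normalize_epochs(split$test))
#> [1] 0.8611111

tab <- class_band_map(model, normalize_epochs(split$test),
                      default_montage("dataset_I_16ch"))
# strongest electrode for class 0 (alpha-band signature on C3), alpha band
sub <- subset(tab, class == 0 & band == "alpha")
sub$electrode[which.max(sub$score)]
#> [1] "C3"
```

The test accuracy (86% here; chance is 1/6 ≈ 16.7%) says the network
recovered the electrode-and-band class structure from 252 training
trials; the topography table localizes each class's distinctive
activation, and `plot_topomap()` renders it as a scalp map. A null
control (`effect_size = 0`) trained identically stays at chance. The
full-scale configuration (`tspnet_config()`, `optimizer_profile("paper")`,
`dataset_profile("dataset_I_16ch")`) preserves the reference dimensions
and ADAM constants verbatim.

A command-line interface wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "tspnet.R", package = "tspnet"))')" \
  simulate --profile desk --effect-size 3 --seed 11 --out epochs.h5
```

with verbs `simulate`, `train`, `eval`, `viz`.

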