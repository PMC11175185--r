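---
title: "Dual-stream sEMG gesture classification: models, assumptions, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-stream sEMG gesture classification: models, assumptions, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semgfusion)
```

## The problem

Surface electromyography (sEMG) records the electrical activity of muscle
motor units through skin electrodes. In myoelectric control, short
multi-channel sEMG segments are classified into hand-gesture classes; the
NinaPro benchmark family fixes the acquisition geometry this package
assumes: sparse electrode arrays (10 channels at 100 Hz for DB1-style data,
12 at 2000 Hz for DB2-style data), guided protocols of 5-s gesture
executions separated by 3-s rests, with per-sample gesture and repetition
label streams.

`semgfusion` implements the complete recognition pipeline — preprocessing,
time-domain feature extraction, a dual-stream convolutional–recurrent
classifier with feature fusion, training and subject-wise evaluation — plus
a synthetic-data generator that stands in for the (large, external)
benchmark download during testing.

## Preprocessing

**High-pass filtering.** Recordings are filtered with a zero-phase
(forward–backward) Butterworth high-pass filter per channel. The literature
this pipeline follows states only that a Butterworth high-pass is applied;
cutoff and order are unstated, so the package defaults to **order 2,
cutoff 1 Hz**: enough to remove offset and motion-artifact drift while
leaving the informative 20–200 Hz surface-EMG band untouched as far as a
100 Hz sampling rate allows. Both are arguments of `highpass_filter()`.
Zero-phase application was chosen so that filtered samples stay aligned
with the per-sample label streams; its magnitude response is the square of
the single-pass response. The design (pole–zero + bilinear transform) was
verified in development against an independent DSP implementation to
machine precision; the in-package frequency-response evaluator
(`filter_response()`) serves as the test oracle for pass-band behavior.
Edge transients are handled with odd-symmetric padding sized from the
slowest pole's decay rate, rather than a fixed short pad.

**Normalization.** Per-channel Z-scores, `z = (x - mu)/delta`, with the
population standard deviation. Statistics are **fitted on training trials
only** (per subject in subject-wise mode) and then applied to validation
data — the source protocol does not specify this, but fitting on everything
would leak validation information; degenerate (constant) channels are
rejected by name.

**Segmentation.** Each contiguous nonzero run of the stimulus stream
becomes one trial of exactly `NT = fs * T` samples (500 at DB1 defaults).
Longer runs are truncated to their first `NT` samples; shorter runs are
zero-padded and flagged rather than dropped, so that trial counts always
match the dataset bookkeeping `N = S * Na * R` (14,040 for 27 subjects,
52 gestures, 10 repetitions). Windows are cut at offsets `0, S, 2S, ...`
with `Nf = floor((NT - W)/S) + 1`. The published geometry (25 windows of
20 samples over a 500-sample trial) forces stride = window length, so
non-overlapping windows are the default; overlapping strides remain
available through `window_spec()`. A 50-ms window at the same stride rule
gives `Nf = 100`, which the same `window_spec()` expresses.

## Time-domain features

The five Hudgins descriptors (MAV, ZC, SSC, WL, RMS, in that fixed order)
are computed per window per channel, giving the `Nf x 5 x C` tensor that
feeds the feature stream. Two choices deserve comment:

- **Thresholds.** ZC and SSC admit amplitude thresholds, unstated in the
  source protocol; the default is 0, the common baseline on Z-scored data,
  and both are configurable in `feature_config()`.
- **SSC at threshold zero.** The conventional formula counts an interior
  point when `(x[i]-x[i-1]) * (x[i]-x[i+1]) >= threshold`. Applied verbatim
  at threshold 0, a perfectly flat neighborhood (zero product) would count
  as a "slope sign change", which contradicts the quantity's definition.
  The package therefore excludes exact-zero products when the threshold is
  0 and applies the `>=` rule verbatim for positive thresholds.

All five features satisfy sign symmetry (`f(-x) = f(x)`); MAV, RMS and WL
are absolutely homogeneous and ZC/SSC scale-invariant at threshold 0 —
these are enforced as property tests, and the vectorized implementations
are checked against naive per-sample loops to 1e-10.

## The dual-stream network

Both streams are **time-distributed over the 25-window axis**: every window
is encoded independently, and only the recurrent head mixes information
across windows.

- *Feature stream*: two stages of 1-D convolution (256 filters; kernels 3
  then 2, stride 1, valid padding: 5 → 3 → 2) each followed by batch
  normalization, ReLU and dropout; flattened per window to width 512.
- *Raw stream*: convolution (kernel 2, stride 2: 20 → 10), an **inner LSTM
  over the within-window sample axis** (256 units, full sequence) to capture
  the short-time sequential structure of the raw signal, a second
  convolution (10 → 5), flattened to width 1280.
- *Fusion and head*: per-window concatenation (width 1792), two
  bidirectional LSTM layers (100 units per direction, sequences preserved,
  width 200), dense(512) + batch norm + ReLU + dropout, and a per-window
  softmax over the classes.

The conv kernels and strides are not stated in the source; they are the
unique minimal valid-mode settings reproducing the published per-layer
lengths, and the implementation refuses non-integer output lengths rather
than silently flooring. The published table's "Flatten (25, 200)" row is
shape-preserving and is kept as a no-op marker in the graph. Activation
placement (ReLU after conv/dense + BN, tanh inside recurrent cells, softmax
at the output) and dropout rates (0.3 conv, 0.5 dense) follow standard
practice because the source lists the ingredients without sites; all are
configurable. L2 (0.01) applies to conv and dense kernels only, mirroring a
`kernel_regularizer`. The per-window softmax head implies per-window
training targets (the trial label broadcast over its 25 windows);
trial-level predictions take the argmax of the window-mean probability
vector, with exact ties broken toward the lowest class index.

The **single-stream ablation** keeps one conv stage on raw windows (no
feature stream, no inner LSTM, no concatenation) ahead of the identical
recurrent head, matching the source's description of "a solitary 1D
convolution layer"; at full DB1 widths it has strictly fewer parameters
than the dual-stream model.

**LSTM conventions.** The published cell equations contain an apparent
typo (the candidate applies the input weight matrix to the previous input
rather than the previous hidden state) and reuse one symbol for input and
recurrent weights. `lstm_cell_step()` — the unit-test oracle — uses the
standard form with distinct input/recurrent matrices per gate; the batched
layer must agree with it to 1e-5 over 100 steps. Gate order is i, f, g, o;
forget-gate biases initialize to 1; kernels are Glorot-uniform.

**Why no framework.** No deep-learning framework ships with the supported
R stack, and the network *is* the package's core contribution, so forward
and backward passes are written out layer by layer. Every gradient path
(convolution via im2col, batch norm, LSTM backprop-through-time in both
directions, fusion split) is validated against central finite differences
(guarded relative error ~1e-6 in development; the shipped test suite
re-checks representative parameters of every layer family).

## Training protocol

Cross-entropy is reported as the **per-sample mean** rather than the batch
sum of the source's formula, so the loss is batch-size invariant; the two
differ by the constant batch-size factor. Optimization is Adam (β₁ = 0.9,
β₂ = 0.999) with base learning rate 1e-4 held for 70 epochs and then
dropped by 0.1. "Step decay" is ambiguous between a single drop and
repeated drops; the default is a single drop, with repeated-interval mode
behind `lr_repeat_drops = TRUE`. Paper-scale settings (batch 64, 500
epochs) are the `train_config()` defaults; desk-scale runs override them
explicitly. Training aborts with a diagnostic on non-finite loss.
Subject-wise evaluation (`run_subject_wise()`) trains an independent model
per subject and averages per-subject trial accuracies, excluding (with a
warning) subjects that have no validation trials.

## The synthetic generator: what it emulates and what it does not

`generate_recording()` produces the *stated world* of a DB1-like
acquisition: 10 channels at 100 Hz, class-major blocks of 5-s activations
separated by 3-s rests, exact per-sample stimulus (0 = rest, 1-based class)
and repetition streams. Each activation is band-limited Gaussian noise
(5–45 Hz by default — the informative band a 100 Hz sampling rate can
carry) scaled per channel by a class-conditional envelope, ramped by a
0.2-s trapezoid to avoid step artifacts, on top of baseline noise
(sd 0.05). This is exactly the amplitude-modulated Gaussian signal model
under which RMS is classically motivated, and it makes all five features
class-informative. The default envelope matrix separates consecutive
classes by a 2× overall gain and rotates a spatial bump across the
electrode array so classes differ in channel profile as well as scale.

The generator deliberately does **not** model motor-unit action potential
shapes, electrode shift, inter-session drift, fatigue, crosstalk, or
class-dependent spectral signatures. A green learnability test therefore
establishes that the pipeline wiring, gradients and optimization work end
to end on separable data — not that the architecture reaches benchmark
accuracy on real sEMG, which requires the external download and
multi-hour training and is explicitly out of the test surface.

Determinism: one seeded stream per call, with `subject_id` perturbing the
seed by a fixed prime multiple, so recordings are bit-identical across
calls and platforms following R's RNG contract.

## Numerical choices and degenerate inputs

- Probability floor 1e-12 before logarithms in the loss; softmax is
  max-shifted for stability.
- Batch-norm: epsilon 1e-5, momentum 0.9 (running statistics), per-filter
  over both batch and position axes for conv outputs.
- Empty trial lists, empty training sets, overlapping repetition splits,
  windows longer than trials, cutoffs at or above Nyquist, constant
  channels, and sub-3-sample windows (SSC undefined) are all rejected with
  specific errors; a recording with no nonzero labels yields an empty trial
  list with a warning.
- Desk-scale tests shrink widths (16 filters / 16 inner / 16 per-direction
  Bi-LSTM / 64 dense) and epochs, never the architecture's structure; the
  learnability acceptance test trains 8 epochs at learning rate 1e-3 —
  well inside the criterion's 50-epoch budget — on 40 training / 10
  validation trials per class.

## Known limitations

- CPU-bound: full DB1-width training (256 filters, 14,040 trials, 500
  epochs) is out of reach of this pure-R implementation's intended use;
  the full-width model is built and shape-verified, while training-path
  tests run at desk scale.
- Intermediates persist as TSV/CSV/JSON rather than HDF5, since no HDF5
  binding is available in the supported stack; the on-disk layout mirrors
  the same datasets and attributes.
- The MAT reader covers real, full numeric arrays (the NinaPro layout),
  not structs, cells, sparse or complex variables.
- Per-window accuracy is logged alongside trial accuracy because the
  source does not state at which granularity its headline number is
  computed; the package treats trial-level accuracy as primary.
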