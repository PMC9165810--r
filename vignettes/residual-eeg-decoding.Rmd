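---
title: "Residual convolutional decoding of motor execution from EEG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residual convolutional decoding of motor execution from EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(reegnet)
```

This vignette is the package's account of its science: the decoding
model, its training procedure, the attribution statistics, what the
synthetic generator does and does not emulate, and the design choices
made where the design was genuinely open. It states no empirical result
that the test suite does not itself compute.

## The decoding problem

The task is three-class classification of 4.5-second epochs of raw
64-channel EEG sampled at 160 Hz (64 × 720 values per trial): rest,
left-fist movement, right-fist movement. The scientifically important
constraint is *cross-subject* evaluation: the test participants never
contribute a single trial to training or model selection, so accuracy
measures transfer to unseen people. For the reference cohort
(109 participants, 4 incomplete ones excluded, leaving 105), 20
participants are drawn as a fixed test set and the remaining 85 are
partitioned into 5 validation folds; `make_split_plan()` reproduces this
scheme for any cohort size, with a seeded shuffle and contiguous
chunking so plans are reproducible and fold sizes differ by at most one.

Epochs are cut at annotation onsets (`epoch_recording()`): sample
indices are 0-based and windows half-open, `[start, start + 720)`, which
keeps the arithmetic unambiguous. Rest epochs are taken one per rest
annotation of the same motor runs — the minimal reading consistent with
the roughly 2:1 rest:movement trial ratio of the reference data.
Recordings at any rate other than 160 Hz are rejected rather than
resampled: resampling would silently change the temporal geometry every
kernel size is expressed in.

## The block system

`build_model()` assembles, in order: one temporal input block
(Conv2Dtype0), ten residual temporal blocks (Conv2Dtype1), one spatial
dimension-reduction block (Conv2Dtype2), five residual depthwise-
separable blocks (Conv2Dtype3), one separable block with pooling
(Conv2Dtype4), and a classifier — 19 blocks in the default
configuration. The residual blocks use identity shortcuts only (no
projections), which is why they are placed exactly where input and
output map counts agree.

Design choices worth recording:

* **Padding.** Temporal kernels — (1, 64) and (1, 16) — use same-length
  zero padding, so the temporal extent stays 720 samples through the
  temporal stack. This is forced by the attribution design: the target
  layer for Grad-CAM must span the full 64 × 720 input geometry. The
  spatial kernel (64, 1) is unpadded and collapses the electrode axis to
  1 ("dimension reduction").
* **Classifier kernel.** Non-overlapping floor-division average pooling
  maps 720 → 180 → 22 time points, so the classifier convolution spans
  (1, 22). The reference description prints (1, 23), which is
  inconsistent with its own pooling widths on 720 samples; the kernel is
  therefore derived from the traced extent at build time and a message
  is logged whenever it differs from 23. Internal consistency beats a
  literal constant here.
* **Activations.** ELU appears only in the two pooling blocks; the
  residual temporal and separable blocks are linear apart from batch
  norm. A config flag (`elu_after_residual`) can insert ELUs after each
  shortcut for experimentation; it is off by default.
* **Biases.** Convolutions carry no bias terms (each is followed by a
  batch norm, which makes biases redundant); the classifier has one.
* **Max-norm.** The constraint ‖w‖₂ ≤ 1 applies to the spatial filters
  only, enforced by projection immediately after every optimizer step.
* **Batch norm numerics.** ε = 1e-5 and running-average momentum 0.1
  (conventional values; the architecture description leaves them open).
  Evaluation mode uses running statistics, so inference is
  deterministic.
* **Input layout.** One implicit input map of shape (channels, time);
  the electrode axis is the "height" of the 2D geometry, matching the
  stated kernel orientations.
* **Initialization.** Weights are Glorot-uniform except the input
  temporal filters, which start as random Gabor atoms — unit-norm
  windowed sinusoids with centre frequencies log-uniform over 4–30 Hz
  and random phase. A filter-bank start is standard practice for
  EEG convolutional decoders: band-limited features exist from the first
  step and training reshapes them, which matters at desk scale where
  the step budget is small. The reference description leaves
  initialization open.

The compiled kernels in `src/convops.cpp` implement the three
convolution shapes (temporal im2col + GEMM, chunked so the expanded
buffer stays cache-resident; spatial reshaped GEMM; direct depthwise
loops). Their correctness is pinned by triple-loop oracles and central
finite differences in the test suite.

## Training

`train_model()` runs plain SGD with momentum 0.9 and a cosine-annealed
learning rate, `lr(t) = lr0 (1 + cos(π min(t, T) / T)) / 2`, stepped per
optimizer iteration (the annealing period is specified in iterations,
29 000 by default) and held at zero beyond the period. The loss is the
mean negative log-likelihood on log-softmax outputs. Preprocessing is
per-channel per-trial z-scoring; the pooled-trial alternative sits
behind `zscore_scope` because the stated motivation for normalization —
impedance and noise differences between electrodes and subjects — points
at the per-channel reading. Augmentation (training folds only, fresh
draws every pass) adds one Gaussian offset per trial (sd 0.10) and one
per channel (sd 0.03); the phrase "noise at trial scale and channel
scale" admits an i.i.d.-per-sample reading too, so both are implemented
(`augment_params(mode=)`) and the choice is recorded in the fit object.
Neither reading is asserted as canonical.

Model selection is by best validation accuracy across epochs — the
reference procedure does not state how the evaluated model is chosen, so
the package makes the standard choice and records the selected epoch.
Class imbalance (rest ≈ 2× each movement class) is left unweighted.
Batches are drawn by reshuffling the pooled training epochs each epoch.
All randomness (splits, initialization, batching, dropout, augmentation,
synthesis) derives from one seed through named substreams
(`derive_seed()`), so every run is exactly reproducible.

## Attribution statistics

Grad-CAM weights the K feature maps of a chosen layer by their
globally-averaged class-score gradients and rectifies the weighted sum.
The differentiated score is the log-softmax output of the target class;
common practice sometimes uses the pre-softmax score instead, so
`score_from = "logits"` offers that alternative and every result object
records which was used. The default target layer is the convolution
output of the last residual temporal block (addressable as e.g.
`"type1.10.conv"`; the post-shortcut block output `"type1.10"` is also
addressable), where the maps still have full 64 × 720 resolution — no
upsampling is ever needed.

Maps are computed for correctly classified trials only, with respect to
the true class. Heatmaps are *not* rescaled per trial: the downstream
statistic compares channel scores to a cross-channel baseline, which any
per-trial normalization would distort. The group statistics treat the
participant as the experimental unit: per participant, heatmaps are
averaged over trials, then over time, giving 64 channel scores whose
mean is that participant's baseline. Per task, each channel's scores are
tested against the baselines with Welch's unpaired two-tailed test, and
the 64 tests form one BH-FDR family. Time-resolved testing repeats this
per time point with a per-time-point baseline (mean over channels at
that time point) and one 64 × T family per task; whether the reference
analysis pooled its family across channels, time, or both is not stated,
and the 64 × T family is the conservative reading adopted here.

The permutation null used for specificity (`permute_channel_scores()`)
permutes each participant's 64 channel scores within participant.
Permuting *task labels* instead would not give a clean null for this
statistic: planted channels would remain above the cross-channel
baseline in every mixed group, so label permutation tests the wrong
hypothesis. Channel permutation destroys exactly the channel–baseline
alignment the statistic measures while leaving each participant's score
distribution and baseline untouched.

## The synthetic generator

`generate_dataset()` emulates the geometry and the one physiological
feature the decoder is supposed to exploit: event-related
desynchronization, i.e. a task-specific attenuation of a band-limited
oscillation. Every channel carries broadband Gaussian noise (sd 1) plus
one sinusoid per epoch — random frequency in the mu band (10–13 Hz) and
random phase, shared by all channels, because volume-conducted scalp
rhythms are spatially coherent — at amplitude 1 scaled by a per-subject
gain ~ Normal(1, 0.1²). On a class's planted channels the amplitude is
multiplied by (1 − effect) for that class's epochs; the default effect
of 0.8 is a strong, clearly detectable attenuation, and the default
planted channels are the contralateral motor electrodes (left fist → C4,
right fist → C3), mirroring where real ERD is expected. Subject
variability enters as a multiplicative gain only — the simplest
mechanism that makes cross-subject splits genuinely harder than
within-subject ones.

What the generator does **not** emulate: volume conduction (no forward
model, channels are spatially independent), ocular/muscle artifacts,
non-stationarities, 1/f spectra, or any temporal structure beyond the
single oscillation. Passing tests on this data therefore demonstrate
that the pipeline can learn and attribute a planted band-power contrast
across subjects — not that it reproduces real-EEG accuracies. Full-scale
accuracy reproduction requires the complete 105-participant cohort and
compute far beyond a desk run, and is deliberately out of scope.

## Problem sizes used by the validation suite

The suite favours exact oracles at tiny geometries (4 channels, 40
samples) where brute force is feasible, plus two full-geometry
experiments chosen as the package's desk-scale study conditions: an
overfitting sanity run (2 training subjects, 4 trials per class,
reduced depth: 2 temporal + 1 separable residual blocks, 30 epochs) that
must reach training accuracy 1.0, and an attribution-recovery experiment
(10 subjects, 12 trials per class, 2 held-out test subjects; reduced
width F1 = 4 and depth 1 + 1 with 16/8-sample kernels; 30 epochs at
learning rate 0.02 with the cosine period equal to the run's 540
iterations) that must exceed 90% test accuracy on unseen subjects, flag
the planted channels as BH-significant versus baseline for their
classes, and flag nothing under the permutation null. The recovery test
differentiates the pre-softmax class score (`score_from = "logits"`) —
with log-softmax scores the softmax normalization absorbs most of the
single-class gradient and the channel contrast loses power — and reads
the test two-sidedly: an ERD surrogate *suppresses* the planted
channel's oscillation, so its Grad-CAM score separates downward from
baseline. Generator parameters are the defaults throughout; only
network width/depth, kernel lengths, the epoch budget and the
desk-scale learning rate are scaled down, with the annealing period
matched to the actual run length as the schedule intends.

## Known limitations

* The EDF+ reader covers the continuous (EDF+C) files used by the
  reference cohort; discontinuous files and non-16-bit variants are out
  of scope.
* Training is CPU-bound R/BLAS; it is meant for desk-scale experiments
  and method development, not for full 85-subject training runs.
* `run_cross_validation()` trains one model per fold sequentially; no
  parallelism is attempted (results stay bit-reproducible).
* Attribution p-values assume approximate normality of per-participant
  mean scores; with very few participants (< 5) the Welch test is
  underpowered and the permutation machinery is the safer reference.
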