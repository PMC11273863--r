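---
title: "Detecting pig vocalizations with fused spectral features and a compact CNN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting pig vocalizations with fused spectral features and a compact CNN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Continuous acoustic monitoring is one of the cheapest ways to follow the
condition of group-housed pigs: calls carry information about stress,
disease, and welfare. The first step of any such system is mundane but
essential — deciding, for every 3-second slice of a farm recording,
whether it contains a pig call at all. `pigvoc` implements a complete,
tested pipeline for this binary decision: preprocessing, spectral
feature extraction and fusion, training-set augmentation, a compact
convolutional classifier, and the two evaluation protocols that matter
for deployment (within-farm cross-validation and leave-one-farm-out
transfer).

The farm recordings the pipeline was designed around are not public, so
the package ships a seeded synthetic generator ("virtual farms") that
reproduces their statistical shape — class balance, per-farm loudness,
distinct background noise — and makes every downstream stage testable.
What passing tests on synthetic data do and do not imply about real farm
audio is discussed at the end.

## Pipeline and model

Recordings enter at 44,100 Hz (16-bit mono or stereo WAV), are averaged
to mono, resampled to the working rate of 22,050 Hz, cut into
non-overlapping 3-s segments, and standardized to exactly
66,150 samples. Loudness is tracked in dBFS, defined here as
`20*log10(RMS)` against a full-scale amplitude of 1 (a full-scale sine
is −3.01 dBFS). RMS rather than peak dBFS is used because per-file
loudness summaries (min/max/average per farm) are only informative on an
RMS scale; peak dBFS would make the min and average columns
near-degenerate for any clip containing a single loud transient.

All feature extractors share one short-time analysis: FFT window 2048,
hop 512, periodic Hann window, centered frames. A 66,150-sample clip
therefore yields `1 + floor(66150/512) = 130` frames for every method —
the centered convention is forced by that frame count. Four projections
of the spectrogram are provided:

* **log-Mel spectrogram** (128 × 130): power spectrogram through a
  Slaney-style triangular filterbank (linear below 1 kHz, logarithmic
  above, area-normalized), log-compressed to dB relative to the clip
  maximum with an 80 dB floor;
* **MFCC** (20 × 130): orthonormal DCT-II of the log-Mel energies,
  first 20 coefficients;
* **chroma** (12 × 130): spectrogram power folded onto the 12 Western
  pitch classes (row 1 = C), each frame normalized by its maximum;
* **tonnetz** (6 × 130): the tonal centroid of the L1-normalized
  chroma on the circles of fifths, minor thirds, and major thirds
  (radii 1, 1, 0.5), so all values lie in [−1, 1].

The fused representation, **Mixed-MMCT** (166 × 130), stacks
[mfcc; mel; chroma; tonnetz]. Two choices here were genuinely open and
are worth recording. First, the stacking order is not dictated by
anything except testability; it is fixed (and exposed) so that row
slices recover the component blocks. Second, each block is z-scored
over its whole matrix before stacking. The blocks live on wildly
different scales — log-Mel in dB spans ~80, tonnetz lives in [−1, 1] —
and an unnormalized stack hands the network a fusion in which one block
dominates the input statistics. Per-block standardization is switchable
(`normalize = FALSE`) for anyone wanting the raw stack.

A third reconciliation concerns the standalone tonnetz input. The
network input table lists tonnetz as 12 × 130, while the tonal centroid
is natively 6-dimensional — and the fused row count 166 = 20 + 128 +
12 + 6 is only consistent with 6. The package resolves this by tiling
the 6 rows twice (`tonnetzStandaloneInput()`) for the standalone
network only: this reproduces both the printed input size and the
printed parameter count, while the fusion keeps the native 6 rows.
Similarly, chroma is described in its source both as max-normalized and
log-compressed; the package follows the normalization contract (column
maxima equal 1 on non-silent frames) and omits the log, which would
destroy that contract.

### The classifier

The network is fixed: three blocks of conv(5×5, stride 1,
size-preserving padding) → ReLU → max-pool(2×2, floor rounding) with
32, 64, and 128 filters, then dropout 0.5, a 1000-unit ReLU dense
layer, and a 2-unit softmax. A clip is called a vocalization exactly
when the first output neuron strictly exceeds the second; ties go to
non-vocalization. Same-padding convolutions and floor pooling are not
free choices: they are the unique combination under which the
closed-form parameter counts reproduce the published complexity table
(e.g. 20 → 10 → 5 → 2 rows and 130 → 65 → 32 → 16 columns for MFCC,
giving a 4096-unit flatten and 4,356,026 parameters → 4.36 M). Biases
are included in every layer; the +2,002 tail of each total requires
them. For the 12-row inputs the closed form gives 2,308,026 → 2.31 M
against a printed 2.30 M — a truncation-vs-rounding inconsistency in
the source table, accepted as a ±0.01 M tolerance.

`countFlops()` reports one forward pass under a `"2xmac"` convention
(multiplies and additions counted separately, bias additions included),
which reproduces the published GFLOPS column to its printed precision
for all four input shapes (0.145, 0.939, 0.086, 1.21); the `"mac"`
convention (half as large) is available because FLOP-counting
conventions are never self-evident.

Training is momentum SGD (momentum 0.9) under a continuous exponential
learning-rate decay `lr0 * 0.9^(step/1000)`, batch size 16, categorical
cross-entropy on the softmax outputs. Cross-entropy is a recorded
choice: the source names the softmax and the task but not the loss, and
cross-entropy is the standard pairing. The decay is continuous rather
than staircase for the same reason (the staircase variant is a config
switch). The engine itself is single-precision (the universal default
for CNN training) with batch-level BLAS gemms; its forward pass and
gradients are verified in the test suite against an independent
double-precision R implementation (forward to ~1e-7, gradients to ~1%
of the layer gradient norm, the expected float accumulation error).

### Configuration profiles

`trainConfig("paper")` carries the published settings: initial rate
5e-4, 50 epochs. At that learning rate the margin grows slowly — on
GPU-scale data that is what the decay schedule is for — so a second
profile, `trainConfig("desk")`, exists for CPU-scale runs on the
synthetic data: initial rate 5e-3, 2 epochs, everything else identical.
The desk profile is a deliberate package design decision, not a claim
about the original experiments; it is the configuration under which the
package's own acceptance runs finish in minutes on one core.

## Evaluation protocols

`crossValidate()` performs stratified fivefold cross-validation
(stratification keeps the designed 50/50 balance in every fold; the
split is seeded) and averages accuracy, precision, recall, and F1 over
folds. The positive class for precision and recall is vocalization,
matching the first-neuron decision rule; macro-averaging would change
nothing detectable on near-balanced results. `robustnessRun()` trains
on the union of two farms (augmented) and evaluates on the third,
held-out farm; `robustnessProtocol()` runs the three pairings — train
(nias, gimje) test jeongeup, train (nias, jeongeup) test gimje, train
(gimje, jeongeup) test nias — and averages.

Provenance is enforced mechanically: every clip carries an id and every
augmented copy a `source_id`; evaluation refuses to proceed if any test
clip's id or source appears among the training ids. Augmentation is
applied after splitting, to training folds only — the arithmetic
(a 3200-clip fold expanding to 16,000 samples) only works on that side
of the split, and the provenance check makes the leakage direction
impossible rather than merely discouraged.

### Augmentation

Four operators, each contributing one new sample per original clip:

* **pitch-shift** by `2^(s/12)` with s ~ U[0, 4] (an integer draw is a
  config option; the source does not say which was used); implemented
  as a phase-vocoder stretch followed by Fourier resampling, duration
  preserved;
* **time-shift** by a uniformly drawn offset with random sign; the
  vacated region is exactly zero. The magnitude range U[0, 1.5] s is a
  package choice (the source says only "randomly determined duration");
  half the clip preserves most content;
* **time-stretch** via phase vocoder, pitch preserved, re-standardized
  to 3 s. The stated stretch factor of 1.0 is literally the identity;
  since a no-op duplicate still satisfies the sample counts but adds no
  diversity, the pipeline defaults to factor ~ U[0.8, 1.2] with the
  literal fixed-1.0 behavior available as `stretchMode = "fixed"`;
* **background noise**: `z = x + w*y` with w ~ U[0, 1] and white noise
  `y` regenerated per clip. `y` is scaled to the clip's RMS so that w
  sweeps the signal-to-noise ratio from clean down to 0 dB; with
  unit-variance noise against clips averaging −25 dBFS, almost every
  draw would bury the signal entirely and a fifth of the training set
  would carry labels unrelated to its content. The mix is peak-
  renormalized only if it exceeds full scale, so w = 0 is exactly the
  identity.

The phase vocoder uses the shared STFT (least-squares inverse with
window-square normalization), which makes the null-parameter operators
exact identities rather than approximate ones — a property the test
suite asserts literally.

## The virtual farms

`builtinFarmProfiles()` defines three sites. Each profile fixes a
background noise color (pink for nias-like, brown for gimje-like, white
for jeongeup-like), a mains/fan hum (120 Hz, 60 Hz, none), an
exponential reverberation smear (12, 25, 5 ms; the kernel keeps the
direct path — a tail-only kernel would lowpass every farm identically
and erase the color distinction), and per-class loudness targets equal
to the published per-farm average dBFS, truncated to the published
min/max. Per-clip loudness is drawn from a Gaussian (sd 1 dB) around
the target, truncated to ±2 dB and to the published bounds — the ±2 dB
truncation is what makes the generator's loudness contract checkable as
a hard property rather than a statistical one.

Vocalization clips add one to four amplitude-enveloped harmonic-stack
bursts (f0 ~ U[200, 1500] Hz, ten harmonics at `1/h` amplitude, burst
duration 0.3–1.2 s) about 12 dB above the bed; non-vocalization clips
add sporadic broadband transients instead. Seeding is counter-based
(a splitmix-style 32-bit mix), so clip i of a dataset is reproducible
independent of generation order.

What the generator emulates: class balance, 3-s clip geometry, per-farm
loudness statistics, cross-farm spectral domain shift, and two-class
separability. What it does not emulate: real pig call taxonomy
(grunt/squeal/scream types), overlapping calls, barn impulse responses
beyond exponential smear, weather and machinery nonstationarity, or
annotation noise. Consequently, the package's passing accuracy checks
demonstrate that the pipeline is implemented correctly and can learn a
separable bioacoustic contrast end to end — they do not certify the
headline accuracies reported on the private recordings, which cannot be
reproduced without that data.

## Numerical choices and degenerate inputs

* Silent clips are legal everywhere: dBFS returns −Inf, the log-Mel
  floor produces a constant matrix, chroma normalization skips silent
  frames, z-scoring of a constant block returns zeros.
* `segmentClip()` drops a final partial window (the datasets are exact
  3-s files); `standardizeLength()` end-pads or end-truncates.
* Pooling uses floor rounding, so every pooled window is a full 2×2;
  inputs whose rows collapse to zero before the third pooling are
  rejected with a shape error.
* The first-neuron decision rule sends exact probability ties to
  non-vocalization (the "otherwise" branch).
* Precision or recall with a zero denominator reports 0 with a
  warning; an all-zero confusion matrix is an error.
* ROC curves sweep the observed vocalization-class scores; AUC is the
  trapezoid rule on the resulting staircase.
* Weight initialization is He-scaled for the convolutional and first
  dense layers and near-zero for the output layer, so initial logits
  start at chance and early optimizer steps train features instead of
  un-doing initialization noise.

## Problem sizes used by the shipped checks

The package's own end-to-end checks run at desk scale, chosen so the
full suite completes on one CPU core in well under half an hour: the
cross-validation check uses one virtual farm at 200 clips per class
with the fused features and 2 epochs per fold; the transfer check
trains on two virtual farms at 100 clips per class per farm (augmented
fivefold) for 1 epoch and evaluates on the third farm; bookkeeping
checks that only count clips (the 4000 → 3200 → 16,000 augmentation
arithmetic) run on lightweight low-rate stand-in waveforms since the
counts do not depend on audio content. The paper-scale configuration
(2000 clips per class, 50 epochs) remains available through
`trainConfig("paper")` and the generator's `nPerClass` argument.

## Known limitations

* The vocalization model is a harmonic-stack stand-in; no claim of
  bioacoustic fidelity is made, and multi-class call typing is out of
  scope.
* Single-precision training is deterministic for a fixed seed on a
  given BLAS, but bit-level results can differ across BLAS builds.
* The phase vocoder introduces the usual transient smearing; operator
  identity properties are exact only at the null parameters.
* WAV support covers PCM 16-bit and float32 — the formats the
  recording chain and the package itself produce.
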