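---
title: "Heart-sound classification with improved MFCC features: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heart-sound classification with improved MFCC features: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiomel)
```

## The problem

Phonocardiography records the acoustic signal of the heart. The first heart
sound (S1) marks the onset of ventricular systole; the second (S2) the onset
of diastole. Murmurs — noise-like components, typically within systole — and
recording artifacts are the two departures from the normal S1/S2 pattern that
this package targets. `cardiomel` implements a complete three-class pipeline
(**normal / abnormal / noise**) over fixed 2-second heart-sound units:
cleaning, feature extraction, neural classification, and a grouped
cross-validation protocol, together with a synthetic phonocardiogram
generator so the whole pipeline is testable without downloading any corpus.

The interfaces accept real corpora (PhysioNet/CinC 2016, the Pascal/Kaggle
set, the Yaseen set) through a manifest CSV (`id,path,source,raw_label`) and
a label map that unifies each corpus' published labels into the three-class
scheme. The shipped default map sends Pascal's `artifact` class to `noise`
and its `murmur`/`extrahs`/`extrastole` classes, like Yaseen's four valve
pathologies, to `abnormal`; `extrahs`/`extrastole` are arguably borderline,
so the map is a plain CSV the user can override
(`default_label_map(path = ...)`).

## Preprocessing

Three steps, in this order:

1. **Low-pass filtering.** A fifth-order Butterworth low-pass at 400 Hz
   removes high-frequency noise while keeping the S1/S2 band. The filter is
   applied with *zero phase*, so S1/S2 timing is untouched; the effective
   magnitude response is the squared Butterworth magnitude
   \(|H(f)|^2 = 1/(1+(f/f_c)^{2n})\) (a tone at the cutoff passes at
   amplitude 1/2, DC at exactly 1). We realise the zero-phase filter in the
   frequency domain: the signal is extended symmetrically (even extension,
   which makes it circularly continuous), its spectrum is multiplied by the
   real weight \(|H(f)|^2\), and the result is cropped back. This matches the
   analytic response exactly at every frequency, whereas a discrete
   forward–backward (filtfilt) realisation of a bilinear-transform Butterworth
   underestimates the stopband gain noticeably at low sampling rates (at
   fs = 8 kHz it attenuates an 800 Hz tone to ~7.5e-4 instead of the analytic
   9.76e-4). The tests pin the analytic value.
2. **Down-sampling to 2000 Hz.** Fourier-method resampling over the same even
   extension: the spectrum is truncated at the new Nyquist frequency, which
   is exact for band-limited signals and alias-safe here because the 400 Hz
   low-pass has already removed everything near the new Nyquist (1000 Hz).
   A polyphase decimator would also do; the FFT method was chosen because it
   preserves tone amplitudes to well under 1% without filter-design edge
   cases. Up-sampling is refused — the pipeline only ever reduces rates.
3. **Cutting into 2-s units.** Consecutive, non-overlapping windows of
   exactly 4000 samples; a trailing remainder shorter than 2 s is discarded;
   recordings shorter than 2 s yield no segments (with a warning); a
   recording of exactly 2 s is kept.

## The improved-MFCC feature

Each 4000-sample segment becomes a 199 × 39 matrix: static mel-frequency
cepstral coefficients (MFCC) concatenated with their first- and second-order
temporal difference coefficients. The stages, each of which has a
direct-summation oracle in the test suite:

* **Pre-emphasis** \(y[n] = x[n] - \alpha x[n-1]\), default
  \(\alpha = 0.97\) (boundary convention \(y[0] = x[0]\)).
* **Framing + Hamming window.** 20 ms frames (40 samples) hopped by 10 ms
  (20 samples), no centring: \(T = \lfloor(4000-40)/20\rfloor + 1 = 199\)
  frames. This frame/hop pair is the defining convention of the feature —
  it is the natural 20 ms/10 ms analysis choice at 2000 Hz and the one that
  yields the canonical 199-frame geometry. The window is
  \(w(n) = 1 - \alpha - \alpha\cos(2\pi n/(N-1))\) with \(\alpha = 0.46\).
* **Power spectrum.** Frames are zero-padded to `n_fft = 256`
  (bin width 7.81 Hz — coarser FFTs produce empty low-frequency triangles
  with only 13 filters over 0–1000 Hz) and
  \(P(k) = |X(k)|^2 / N_\mathrm{FFT}\) is kept one-sided
  (\(k = 0..128\)).
* **Mel filter bank.** \(M = 13\) triangular filters with unit peaks whose
  15 edge frequencies are uniformly spaced in mel
  (\(\mathrm{mel}(f) = 2595\log_{10}(1+f/700)\)) between 0 Hz and Nyquist,
  then quantised to FFT bins. With unit peaks and shared edges, adjacent
  triangles sum to exactly 1 at every interior bin — the bank's
  normalisation property, tested to 1e-6.
* **Log band energies.** Natural logarithm of the filter-bank outputs with a
  1e-10 floor so silent frames stay finite. (The mel map uses the base-10
  logarithm with the standard 2595 constant; the band energies use the
  natural logarithm — the two logarithms play different roles and both
  conventions are pinned by tests.)
* **Cepstra.** \(C(n) = \sum_{m=1}^{13} S(m)\cos(\pi n (m-0.5)/13)\) for
  \(n = 1..13\): the DCT-II family with the 0th (pure energy) coefficient
  excluded, which makes the cepstra exactly invariant to per-segment gain —
  a property the tests exploit.
* **Deltas.** \(D(t) = \sum_{i=-2}^{2} i\,C(t+i) / 10\) per coefficient,
  with edge frames replicated so the frame count is preserved and a
  time-constant input has exactly zero delta. Applying the operator twice
  gives the second-order coefficients.

The static, delta and delta-delta blocks are stacked column-wise into the
199 × 39 network input:

```{r features}
seg <- synth_recording("abnormal", 2, synth_config(seed = 1))
fm <- improved_mfcc(seg$samples)
dim(fm$stacked)
```

A cross-check against an independent numpy implementation of the same
definitions (different language, different FFT) requires per-coefficient
correlation above 0.999 on synthetic audio; exact equality is not expected
between implementations because scaling conventions in published MFCC
variants differ.

## Models

Architectures are data: dash-separated structure strings (e.g.
`"LSTM (64)-Drop (0.5)-FC(64)-FC (3)"`) parsed into layer lists, from which
`build_model()` creates trainable networks and `count_parameters()` totals
every parameter array. No deep-learning framework exists for R in this
stack, so the package carries its own small engine: im2col convolutions,
depthwise-separable convolutions, batch normalisation, max pooling, dropout,
dense, LSTM and GRU layers with full backpropagation (verified against
central finite differences in the tests), softmax cross-entropy, and Adam.
The heavy kernels are C++ (Rcpp/Armadillo, BLAS-backed GEMM).

Conventions, chosen once and documented here because the printed
architecture table leaves them open:

* **Gate parameterisations.** The LSTM uses the standard four-gate form with
  one bias vector per gate — total \(4((F+U)U+U)\), which reproduces the
  published 30,979 for \(F=39, U=64\) plus the two dense layers. The GRU
  uses the *dual-bias* convention (separate input and recurrent bias per
  gate, the form used by fused GPU kernels) — total \(3(FU+U^2+2U)\),
  the only convention consistent with the published 24,515.
* **Padding and pooling.** Convolutions use same padding and stride 1;
  pooling is 3×3 with stride 3 and *same* (ceil) padding. Valid-padding
  pooling cannot realise the published residual network at a 199 × 39
  input — the width path 39 → 13 → 4 → 1 cannot pass a fourth 3×3 pool —
  so ceil pooling is the only consistent reading.
* **Residual blocks.** `residual {Conv [k,(1,1)]-BN} … add` is built
  Xception-style: the braced projection (1×1 convolution + batch norm) runs
  from the block input with stride equal to the main path's pooling factor,
  so shapes match exactly at the `add`. Shape mismatches are build errors
  that name both shapes.
* **Activations.** ReLU after every main-path batch norm, after
  convolutions not followed by batch norm, and after hidden dense layers;
  no activation inside projection branches, after the logit-producing layer,
  or on recurrent outputs.
* **Separable convolutions** are depthwise 3×3 (multiplier 1) plus pointwise
  1×1, each with a bias. Parameter totals count batch-norm running
  statistics, the usual layer-summary convention. Under these conventions
  the residual network totals 36,075 parameters — close to the ~35.9k a
  biasless-depthwise count gives, while the published table prints 52,339
  for that row; the table's counting convention for that row is not
  recoverable (its two plain-CNN rows print different totals for identical
  structure strings), so the residual-network total is reported, not
  enforced. The plain CNN baseline totals 97,539, matching the table's
  CNNa row.
* **Optimiser.** Adam (lr 1e-3, \(\beta_1=0.9\), \(\beta_2=0.999\)),
  batch 32, 30 epochs by default, categorical cross-entropy; one integer
  seed controls initialisation, shuffling and dropout, making training runs
  bit-reproducible. Batch-norm running statistics use momentum 0.9
  (\(\epsilon = 10^{-3}\)): desk-scale runs take a few hundred optimiser
  steps, and a slower momentum (e.g. 0.99) leaves inference statistics stale
  relative to the trained weights.
* **Input scaling.** `train_model()` standardises each of the 39 feature
  columns with training-set statistics; the scaler is stored in the fitted
  model and re-applied at prediction.

## Evaluation protocol

`make_splits()` reserves 20% of *recordings* as a fixed test pool
(stratified by class with largest-remainder rounding, so the pool is exactly
`round(0.2 n)`), then partitions the remainder into five stratified
validation folds. Splitting is always by parent recording, never by 2-s
segment: segments of one recording are near-duplicates, and letting them
straddle the test boundary would inflate accuracy. `cross_validate()` trains
one model per fold on the other four folds (class-balanced), evaluates each
on the fixed test pool, and reports the arithmetic mean of the five test
accuracies alongside per-fold reports.

Class imbalance is handled by `balance_classes()`: minority-class segments
are oversampled with replacement and each copy is lightly augmented — a
random circular time shift up to 0.2 s and a gain jitter of ±3 dB, both
label-preserving for quasi-periodic signals. Balancing touches training
folds only.

Metrics come from the 3×3 confusion matrix: accuracy is trace/total;
sensitivity \(TP/(TP+FN)\), specificity \(TN/(TN+FP)\) and precision
\(TP/(TP+FP)\) are computed one-vs-rest per class and macro-averaged
(the unweighted mean — single published summary values for a three-class
task do not identify the averaging, so per-class values are always reported
alongside). Zero denominators yield `NaN` with a warning rather than an
error. Early stopping on validation loss is available (`patience`) but off
by default; fixed-epoch training is the reference behaviour.

## The synthetic generator

`synth_recording()` is a stylised signal model, not a physiological
simulator. Normal recordings are exponentially damped S1 (60 Hz) and S2
(90 Hz) tones (decay 0.04 s; S2 shorter and weaker) placed on a jittered
0.8 s cycle (≈75 bpm) with a 0.3 s systolic interval, over a faint broadband
floor; abnormal recordings add band-limited murmur noise (150–400 Hz)
confined to each systolic interval at a configurable tone-to-murmur ratio
(default 5 dB); the artifact class is broadband noise or a random spike
train with no periodic structure. Peak amplitude is normalised to 0.9 and
every signal is a deterministic function of (label, seed); per-file seeds
derive from one master seed.

What it emulates: the class-defining structure (periodic S1/S2, systolic
murmur band power, aperiodic artifacts) at realistic rates and frequencies,
below 500 Hz for heart-sound classes so the 400 Hz low-pass cannot erase
class information. What it does not: sensor transfer functions, respiration,
S3/S4 sounds, pathology diversity, or the heavy-tailed noise of clinical
recordings. Tests passing on synthetic data therefore demonstrate that the
pipeline is implemented correctly and that the networks can learn a
separable three-class audio task end-to-end — not that the published
real-data accuracy transfers; reproducing those numbers requires the
external corpora, which plug in through the same manifest interface.

Problem sizes used by the test suite were chosen to exercise the full
protocol at desk scale: the learnability check trains the residual network
for 15 epochs on 200 recordings per class (480 training / 120 test segments)
across five seeds and requires ≥90% test accuracy in at least four of them;
the cross-validation and determinism tests use 8–10 recordings per class
with small recurrent models.

## Numerical choices and degenerate inputs

* Log floor 1e-10 for silent bands; softmax is max-shifted; cross-entropy
  clips probabilities at 1e-12.
* The delta denominator for k = 2 is exactly 10; edge replication keeps
  constants at zero delta.
* Mel edge bins use `floor((n_fft + 1) * f / sr)`; a filter whose three
  edges coincide raises a configuration error advising a larger `n_fft`.
* Recordings shorter than one segment yield an empty result (with a
  warning), not an error; an empty class in balancing is an error.
* Confusion-matrix divisions by zero yield `NaN` with a warning.
* WAV I/O supports PCM16/PCM32 and IEEE float mono; integer samples are
  scaled by full scale into [-1, 1]; out-of-range samples are clipped at
  write time.

## Known limitations

* The engine is CPU-only and sized for desk-scale experiments (minutes per
  training run), not for the full fused real corpora.
* The residual network's published parameter total is not reproduced
  (see above); its architecture is.
* The generator's classes are deliberately separable at default settings;
  `murmur_snr_db` can be lowered to create harder regimes, but no claim is
  made that difficulty then matches clinical data.
* Only the three-class unified scheme is implemented; finer-grained valve
  pathology labels are collapsed by the label map.
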