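---
title: "From multi-channel sEMG to gesture labels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From multi-channel sEMG to gesture labels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgimage)
```

## The problem

Surface electromyography (sEMG) measures muscle electrical activity at the
skin. A 16-channel forearm armband sampling at 2000 samples/s per channel
sees each hand gesture as a distinct spatial pattern of activity across its
electrodes, because different gestures recruit different parts of the
forearm muscle group. `emgimage` implements a complete recognition
pipeline around that idea: filter the raw signals, cut them into short
classification records, render each record as a small grayscale image in
one of three ways, and classify the images with a compact convolutional
network. A comparison harness measures how recognition accuracy depends on
(a) the number of channels (8 vs 16) and (b) the signal-to-image encoding.

Because the human dataset the design is based on is not publicly
deposited, the package ships a synthetic generator that emulates the
acquisition protocol; everything downstream is exercised against it.

## Synthetic sEMG generator

Each recording is the hold phase of one gesture repetition. Per channel
$c$ the model is

$$x_c(t) = a_c \, e(t)\, n_c(t) + A_{50}\sin(2\pi\,50\,t + \varphi)
  + d + \sigma w_c(t),$$

where $n_c(t)$ is Gaussian white noise band-passed to 20–450 Hz (the band
that carries most surface-EMG energy) and normalized to unit RMS, $e(t)$
is a raised-cosine on/off envelope with 0.25 s ramps around a unit
plateau, $a_c$ is the gesture's activation weight on channel $c$,
$A_{50}$ a 50 Hz powerline amplitude with per-recording random phase,
$d$ a DC offset and $w_c$ white measurement noise. Defaults follow the
acquisition protocol the pipeline targets: 2000 sps, 16 channels, 10 s
holds, 3 s rests, 10 repetitions per gesture, 30 subjects; amplitudes
default to $A_{50} = 0.5$, $d = 0.3$, $\sigma = 0.05$ relative to the
unit-RMS carrier — visible contamination, high signal-to-noise, which is
what a careful armband recording looks like after hardware filtering.

The ten gesture activation vectors are fixed constants: smooth bumps
centred at ten evenly spaced positions around the armband ring (width
$\approx$ 2.4 channels, plus a 0.05 co-activation floor), giving pairwise
cosine similarity below 0.95. Subject-to-subject variation is a fixed
multiplicative lognormal perturbation of the activations
($\sigma = 0.15$) drawn from a subject-derived seed — a minimal model of
electrode placement and anatomy differences. We deliberately do not model
motor-unit action potentials, recruitment, fatigue, or electrode shift;
the generator reproduces the *statistical* structure the pipeline relies
on (band-limited energy, gesture-specific spatial patterns, powerline and
DC contamination), not the physiology. Passing tests therefore validate
the pipeline's mechanics and its ability to exploit spatial activation
patterns; they say nothing about accuracy on real human data.

All randomness derives from one master seed through a deterministic
stream-splitting hash, so datasets are bit-reproducible.

## Preprocessing

Two software filters mirror the acquisition front end:

* **50 Hz notch** — Butterworth band-stop, stop band 49–51 Hz, overall
  order 4 (order 2 per edge; the order is our choice, the cutoffs are the
  design's). Applied forward–backward by default (zero phase), which
  squares the magnitude response and avoids group-delay distortion of the
  250 ms records; a causal mode exists for streaming parity. The designed
  single-pass response is $\le -20$ dB at 50 Hz and $\ge -1$ dB at 10 and
  100 Hz.
* **DC block** — single-pole recursive high-pass
  $y[n] = x[n] - x[n-1] + R\,y[n-1]$ with $R = e^{-2\pi f_c/f_s}$,
  $f_c = 2$ Hz, run causally (it emulates a hardware stage). A constant
  offset decays geometrically; over a 10 s record the residual mean in the
  second half is far below 1%.

Zero-phase filtering pads each channel with its own point reflection
(30 coefficient-lengths) before the forward and backward passes, so
startup transients of the narrow notch do not leak into the first
segments. The chain runs on whole recordings before windowing. The
hardware's 1000 Hz low-pass is not re-applied in software: at 2000 sps it
sits at the Nyquist frequency and would be a no-op.

## Segmentation and the three encoders

Real-time myoelectric control budgets roughly 300 ms of total latency, so
one classification record is **250 ms** of signal. Records are cut
*non-overlapping* (stride = 250 ms); the finer 100 ms window with 50 ms
hop operates inside a record during STFT framing. Keeping records disjoint
means a train/test split can never share samples between partitions.

* **Time-domain images.** Each channel's 500 samples are low-pass filtered
  (zero-phase Butterworth, cutoff at 90% of the post-decimation Nyquist)
  and decimated by 2, giving rows × 250 pixels: 16×250 or 8×250. The
  decimation convention is our resolution of an ambiguity — 250 ms at
  2000 sps is 500 samples, and halving is the only reading that produces
  the stated 250-column image; an alternative (a 125 ms span) cannot be
  ruled out from the source description.
* **Spectrogram images.** Per channel, a Hann-tapered 200-sample window
  slides by 100 samples (4 frames), each frame zero-padded to
  `nfft = 256` — the next power of two above the window, forced by the
  129 = 256/2 + 1 bin count — and the one-sided magnitudes form a 4×129
  matrix. Channel matrices are stacked row-wise in ascending channel
  order: 32×129 (8 ch) or 64×129 (16 ch).
* **Feature-enhanced spectrograms.** An auxiliary signal, the *pointwise
  maximum across channels* at each sample, is appended as a final channel
  (9 or 17 channels), then encoded as above: 36×129 or 68×129. The source
  description could also be read as per-channel scalar maxima; we
  implement the pointwise cross-channel reading, which yields an actual
  auxiliary *signal* and matches the stacking geometry.

Pixels are min–max normalized per image to [0, 1] (linear magnitude; a
`log1p` flag exists). A constant image maps to all zeros.

## The two CNNs

Both classifiers share one backbone:

| layer | time-domain variant | spectral variant |
|---|---|---|
| conv 3×3, 32 kernels, stride 1, pad 1 + BN + ReLU | — | — |
| max pool | 3 columns × 1 row | 2 × 2 |
| conv 3×3, 64 kernels, stride 1, no pad + BN + ReLU | — | — |
| max pool | 2 columns × 1 row | 2 × 2 |
| flatten → FC(128) → FC(10) → softmax | — | — |

Pooling geometry was the one genuinely open design point. Read as
(rows × cols), "3×1" pooling would collapse an 8×250 image to 2 rows,
which the following unpadded 3×3 convolution cannot accept — the
architecture would be infeasible for the 8-channel condition. We therefore
read the pool sizes as (width × height): the time-domain variant pools
along time only, preserving its few channel rows, and both the 8- and
16-row inputs pass through cleanly. The spectral 2×2 pools are unaffected.
Pooling is non-overlapping with floor division; remainders are dropped.

The same spectral architecture accepts 32-, 36-, 64- and 68-row inputs;
only the first fully connected layer's width changes, which is verified as
a parameter-count identity in the tests.

Training is mini-batch Adam (learning rate 1e-3, batch 32, 10 epochs by
default) on the softmax cross-entropy, with batch statistics during
training and exponential running statistics (momentum 0.1) for inference.
On the separable synthetic data the loss plateaus within a few epochs, so
10 is a comfortable default. The engine is written in RcppArmadillo —
im2col + GEMM convolutions in single precision with fused
batch-norm/ReLU passes — because no neural-network framework is part of
the package's dependency set and the two small architectures do not need
one. He-scaled Gaussian initialization and data shuffling draw from an
explicit `mt19937` seed, so training histories are bit-reproducible.

Numerical corner cases: softmax subtracts the per-column maximum before
exponentiation; batch-norm variance is clamped at zero with
$\varepsilon = 10^{-5}$; max-pool ties resolve to the first (lowest
linear index) element; all-zero or constant images are valid inputs and
produce valid probability vectors.

## Evaluation

A report is a confusion matrix (rows = true gesture, columns = predicted;
a transpose flag exists for plotting conventions that swap axes),
per-class accuracies $100\,C_{ii}/\sum_j C_{ij}$, and the **average
accuracy** defined as the *unweighted mean of per-class accuracies* — the
convention under which a published per-gesture accuracy table's Average
row is exactly the column mean of its cells, which the tests verify
against the shipped `reference_accuracies()` worked example. Displayed
percentages round half-up to 1 decimal (`round_half_up()`), matching how
such tables are printed; an epsilon of 1e-9 absorbs binary representation
of values like 95.55.

`compare_conditions()` runs the full harness: for each condition in
{time-domain, spectrogram, enhanced} × {8, 16 channels} it encodes,
splits, trains and evaluates with one shared seed. The 8-channel
condition keeps the 0-based even electrodes (every other contact around
the armband), the subset that stays evenly distributed. The train/test
split holds out whole (subject, repetition) groups (80/20, at least one
group), so provenance never straddles the boundary; each group contains
every gesture, keeping both partitions class-balanced.

## Problem sizes

The demonstration scale used by the test suite and the acceptance script
is 2 subjects × 10 gestures × 3 repetitions with 2.5 s holds — 600
disjoint 250 ms records per condition, split 500/100 — which the package
treats as its reference configuration for desk-scale experiments. At this
scale and the default training configuration every condition reaches
high held-out accuracy (chance is 10%); at the full protocol scale
(30 subjects, 10 s holds, 10 repetitions) the same code paths apply
unchanged but run far longer. Because the synthetic classes are
spatially well separated by construction, condition accuracies saturate
near 100% and the harness does not reproduce the *ordering* of encoders
observed on real data; it demonstrates the mechanics, determinism, and
chance-level separation of the comparison, not encoder superiority.

## Known limitations

* The generator's simplifications (no MUAP shapes, no fatigue, no
  electrode shift, stationary activation within a hold) make the
  classification task easier than real sEMG.
* The averaging of repetitions mentioned in the source protocol
  description ("average values for the 10 repetitions") is ambiguous —
  what is averaged and how it is aligned is unstated — and is not
  emulated; the pipeline trains on all windowed records.
* Only the `adam` optimizer and the two fixed backbones are provided;
  hyperparameter search, augmentation and transfer learning are out of
  scope.
* Whether notch filtering preceded or followed segmentation in the
  original workflow is unstated; this pipeline filters whole recordings
  first, which is the cleaner choice for zero-phase filtering.
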