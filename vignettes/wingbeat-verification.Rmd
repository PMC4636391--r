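---
title: "Optoacoustic wingbeat verification: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optoacoustic wingbeat verification: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entotrap)
```

## The problem

Monitoring the olive fruit fly (*Bactrocera oleae*) relies on traps that must
be inspected by hand. An instrumented McPhail trap automates the count: an
infrared emitter/photoreceptor pair spans the trap entrance, and an insect
flying through modulates the received light at its wingbeat frequency. The
resulting signal is audio-like; its harmonic spectrum — the fundamental
wingbeat frequency plus the relative weights of its harmonics — acts as a
coarse biometric signature of the species. `entotrap` is a software twin of
that device: it generates synthetic wingbeat events with the statistical
structure the trap assumes, reproduces the firmware's detection and feature
pipeline, and implements the open-set verification rule and its evaluation.

## Signal model

A wingbeat event is modelled as a harmonic sum

$$x(t) \;=\; e(t)\, m(t) \sum_{h=1}^{H} w_h \sin\!\big(h\,\phi(t) + \varphi_h\big),
\qquad \phi(t) = 2\pi\!\int_0^t f_0(\tau)\,d\tau ,$$

where the fundamental $f_0$ is drawn uniformly from a species band
(*B. oleae* 170–210 Hz; honey bee 140–150 Hz), $w_h$ are species-specific
harmonic weights, $e(t)$ is a raised-cosine onset/offset envelope with ramps
of 10% of the event duration (avoiding spectral splatter at the edges), and
$m(t)$ is optional slow amplitude modulation of depth `amDepth` emulating
maneuvering passes. $f_0(\tau)$ drifts slowly around the drawn value with
scale `f0JitterSd`. Harmonic phases $\varphi_h$ are drawn per event; the
magnitude-spectrum features are phase-invariant, so this choice is
inconsequential downstream. White Gaussian noise is added after peak
normalization; the default `noiseSd = 0.01` corresponds to the very high
signal-to-noise ratio of the optical sensor (roughly 30–40 dB below a
full-scale pass).

Event durations follow the two observed behavioral flight modes: fast direct
crossings of 30–50 ms and slow strolling passes of 50–300 ms, equally likely
by default. The 10-bit ADC of the hardware is emulated by `quantize()`, a
mid-rise uniform map of $[-1, 1]$ onto $2^{10}$ codes.

Presets beyond *B. oleae* and the honey bee are modelling choices, not field
measurements: the mosquito preset (400–650 Hz, fast-decaying harmonics)
provides a well-separated non-target; `chironomidae` shares the *B. oleae*
fundamental band but redistributes harmonic power (partial resemblance); and
`l_aristella` is deliberately *identical* to the *B. oleae* preset, so that
the known failure mode — two species with fully overlapping spectra — is
reproducible in kind.

## The firmware pipeline

1. **Acquisition and trigger.** The stream is scanned in non-overlapping
   512-sample frames at 4 kHz (128 ms). A frame whose RMS strictly exceeds a
   pre-defined threshold triggers an event; consecutive triggered frames are
   merged into one event (a slow pass spans several frames), keeping the
   first triggered frame as the event frame. The threshold default is 0.05,
   i.e. 5× the RMS of the default noise floor; `calibrateRmsThreshold()`
   recomputes it from any noise-only segment.
2. **Features.** The frame is Hamming-windowed (periodic convention,
   $w_k = 0.54 - 0.46\cos(2\pi k/n)$, fixed so signatures are bit-stable),
   transformed by a 512-point FFT, and the magnitudes of the first 256 bins
   (bin width $4000/512 = 7.8125$ Hz) are kept — for a real signal the upper
   half is redundant, which also reproduces the published feature-matrix
   shape of 256 columns. The lowest `dcCutBins = 3` bins (≈ 0–23 Hz) are
   zeroed, emulating the analog high-pass that removes the insect's slow
   body-movement component; the hardware cutoff is not documented, so the
   count is configurable. The vector is then divided by its Euclidean norm.
   Unit-L2 normalization makes the signature invariant to analog gain — the
   property the firmware normalizes for. Frames shorter than 512 samples are
   windowed over their own length and zero-padded; whether the original
   firmware normalized over 512 or 256 bins is not recoverable, and the
   choice only scales all signatures by a common constant, so normalization
   is over the kept 256.
3. **Verification.** A species codebook is `K = 4` prototype spectra
   obtained by Lloyd's K-means (Euclidean objective — "K-means" names the
   standard algorithm, while verification deliberately uses the absolute
   norm, matching the device) with seeded k-means++ initialization, 10
   restarts, best within-cluster sum of squares kept. Centroids of unit
   vectors are not unit vectors, so prototypes are re-normalized back into
   signature space. The distance of a signature to the codebook is the
   minimum L1 (absolute-norm) distance over prototypes. The acceptance
   threshold is calibrated on the training spectra as
   $\mu_d + 3\sigma_d$ of their minimum distances ($\sigma_d$ is the sample,
   $n-1$, standard deviation; convention fixed here). A distance exactly
   equal to the threshold is accepted: only distances *more than* the
   threshold mark a non-target. Calibration uses the same spectra that
   produced the prototypes, as the device's procedure describes.

Two calibrated codebooks turn verification into closed-set classification:
the smaller minimum distance wins, ties going to the first codebook with a
warning.

### Where training spectra come from

Reference spectra are collected as whole passes through a bench sensor, not
as trap-triggered frames: `synthSignatures()` emulates this, featurizing each
complete event in isolation (the device's reference set held 403 such
recordings). This matters. Training on trap-triggered frames mixes complete
passes with frame-boundary fragments, inflating the spread of training
distances and therefore the $\mu + 3\sigma$ threshold — enough, in our
measurements, to push it into the distance range of mosquito spectra.

### The discarded pre-trigger buffer

The firmware analyzes only the 512-sample frame that fired the trigger; the
samples of the same pass that fell in earlier frames are discarded, and a
pass straddling a frame boundary yields a fragmented spectrum. This is a
known defect of the device, to which it attributes part of its
misclassifications. `detectEvents()` replicates the defect by default. With
`pretrigger = TRUE` it instead keeps each event's full extent (the frame
preceding the trigger plus all triggered frames), and `eventToSignature()`
takes the contiguous 512-sample window of maximal energy, so the FFT covers
the pass rather than an arbitrary boundary. On synthetic mixtures the
frame-only replica reaches an end-to-end target F1 of roughly 0.85–0.92,
while full-extent capture reaches 0.95–1.0; the package's end-to-end
acceptance study therefore runs with `pretrigger = TRUE` and reports the
full-extent figure.

## Evaluation machinery

`precisionRecallF1()` implements $P = T_p/(T_p+F_p)$, $R = T_p/(T_p+F_n)$
and their harmonic mean, with undefined metrics returned as `NA` with a
warning rather than silently zeroed. Per-class scores are aggregated by
support weighting (`weightedAverage()`), the "Avg/total" row of the standard
report; macro averages are also available. Printed two-decimal tables use
round-half-to-even; two cells of the published tables do not recompute from
their own rounded per-class entries (the honey-bee table's average precision
and the midge table's average recall) and are treated as rounding artifacts,
flagged in the tests rather than forced.

The model-based baseline, `crossvalClassify()`, follows the stated protocol
literally: the dataset is shuffled once, then 10 *independent random 80/20
splits* are drawn — repeated random sub-sampling, not partitioned k-fold —
and held-out accuracy is averaged. Hyperparameters are unstated in the
source description, so common library defaults are frozen: RBF SVM with cost
1, no re-scaling (the features are already unit-norm) and
$\gamma = 1/(p\,\mathrm{var}(X))$; random forest and extremely randomized
trees with 200 trees; gradient boosting with 50 rounds, depth 3, learning
rate 0.3, single-threaded for reproducibility.

## The trap runtime and telemetry

`runTrap()` composes detection, featurization and verification over a stream
and returns a per-event decision log plus a telemetry record: total events,
target matches, and pass-through sensor metadata (temperature, humidity, GPS
coordinates, battery level — metadata only; temperature compensation of
spectra is out of scope). `buildReport()` renders the record as a flat JSON
object or a single versioned SMS-style line of `key=value` fields capped at
160 characters (an over-long payload is an error, never a silent
truncation); `parseReport()` is its exact inverse, validating ranges and
naming any missing field. No network transport is implemented — payloads go
to files or stdout. The message grammar is this package's own, version-tagged
`ETv1`; the original device does not publish one.

## Numerical and degenerate-input choices

* All-zero spectra (possible after the DC cut if a frame holds no signal)
  raise a degenerate-spectrum error; the runtime counts such events but never
  matches them.
* `quantize()` clips to $[-1,1]$ before coding; re-quantizing is the
  identity, and the round-trip error is below one LSB of the mid-rise grid.
* K-means restarts that lose a cluster are discarded; at least one restart
  must survive.
* Seeds: every stochastic entry point takes an explicit `seed` and restores
  the caller's RNG state, so pipelines are reproducible bit for bit.

## Study sizes used by the tests and acceptance script

Codebooks are trained on 403 synthetic reference recordings (the device's
own reference-set size) with K = 4. End-to-end verification uses 100-event
streams mixing target and mosquito passes 74:26, the support ratio of the
published easy-pair experiment. Two-codebook experiments use 403 training
and 400 test signatures per run; fundamental-recovery checks use 100 draws
per species preset. These sizes make every check run in seconds while
matching the published experiment scales where they are stated.

## What the synthetic data does and does not show

The generator reproduces the *structure* the method assumes — species-banded
fundamentals, species-specific harmonic envelopes, two duration modes,
amplitude modulation, additive noise, quantization. It does not model the
optics (occlusion geometry, angle-dependent amplitude), temperature drift of
wingbeat frequency, inter-individual variation within a species, or real
field noise spectra. Passing tests therefore demonstrate that the pipeline
is implemented correctly and behaves as published *under its own
assumptions*; they do not re-establish the published field accuracies, which
depend on the original recordings. Correspondingly, the absolute
cross-validation accuracies published for the hard species pair
(0.725–0.738) are not reproduction targets: on synthetic data where the two
species are generated identically, every classifier sits at chance, and the
two-codebook experiment reproduces exactly that failure mode.

## Known limitations

* The verification margin between the target band and a 400–650 Hz
  non-target is a few L1 units; with unlucky training draws the
  $\mu + 3\sigma$ threshold admits 5–15% of mosquito-preset spectra —
  consistent with the published mosquito recall of 0.86.
* Signatures of passes shorter than ~50 ms are strongly smeared by the
  rectangular observation limit; they dominate both the training-distance
  tail and the residual errors.
* Only mono 16-bit PCM WAV is read; other encodings must be converted first.
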