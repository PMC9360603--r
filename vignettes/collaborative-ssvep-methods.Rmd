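---
title: "Collaborative SSVEP classification: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collaborative SSVEP classification: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A steady-state visually evoked potential (SSVEP) brain–computer interface
presents a user with several stimuli flickering at distinct frequencies;
the occipital EEG of a user fixating one stimulus contains a periodic
response at that frequency and its harmonics, and decoding which stimulus
was attended amounts to 4-way classification of short EEG epochs. A
*collaborative* BCI (cBCI) records several users fixating the same
stimulus simultaneously and decides jointly. This package implements the
centralized variant: the users' spectral features are fused into a single
input and classified by one compact convolutional network, with a
two-stage transfer-learning protocol supplying the network weights from a
large source domain before fine-tuning on a small target set.

The protocol modelled throughout is a four-target display flickering at
8.6, 10, 12 and 15 Hz with phases 1.35π, 0.35π, 0.9π and 0.35π, recorded
from O1/Oz/O2 at 256 Hz for 4 s per trial.

## Feature model

Each epoch is band-pass filtered (4th-order Butterworth, 5–40 Hz,
applied forward–backward), truncated to the analysis window, transformed
channel-wise by an FFT magnitude spectrum with no taper and no padding,
restricted to the half-open band [6, 32) Hz, and min–max normalized per
channel:

$$\mathrm{Input}_c = \mathrm{minmax}\left(\left|\mathrm{FFT}(X_c)\right|\,\big|_{6 \le f < 32}\right), \quad c \in \{O1, Oz, O2\}.$$

Numerical conventions that matter:

* **Half-open band.** With a 3 s window the bin spacing is 1/3 Hz and
  `[6, 32)` retains exactly 78 bins, matching the printed network input
  (3, 78). A closed interval would give 79. Whether the original band
  included 32 Hz and excluded 6 Hz (also 78 bins) is indeterminate; the
  half-open-low convention is this package's documented choice.
* **No taper, no padding.** The printed bin count only matches the
  raw-length transform, so none is applied; Parseval equality of the
  one-sided spectrum is asserted in the tests.
* **Zero-phase filtering.** Causality is not specified by the protocol;
  forward–backward filtering avoids group-delay distortion and is
  standard offline practice. The `signal` package's transfer-function
  `filtfilt` is used; at order 4 with these band edges the design is
  numerically unproblematic (verified by the magnitude-response tests).
  Feature extraction operates on the filtered signal.
* **Normalization per channel per epoch**; a constant channel maps to
  zeros so outputs stay bounded. Normalization precedes fusion, because
  averaging is defined on normalized features.
* **Short windows.** Bin counts for other windows follow the same rule
  (2 s → 52 bins, 1.6 s → 42 bins); the networks are parameterized by
  the bin count B rather than fixed at 78.

## Fusion operators

Three shape-level operators combine K subjects' normalized 3 × B
matrices for the same trial:

* **parallel** — stacking along the channel axis → (3K) × B ("more
  feature lead channels");
* **serial** — concatenation along the frequency axis → 3 × (K·B);
* **average** — element-wise mean → 3 × B, consumable by the
  single-subject network.

Member order is the caller's subject order and is recorded in the fused
object. Note the printed two-person serial input of 234 columns is not
derivable from 2 × 78 = 156 under any stated rule; the generic K·B rule
is implemented and a network can be built at any explicit input length
(including 234) for structural comparison.

## Network architectures

Three compact EEGNet-style stacks, reproduced exactly from the printed
layer tables and verified cell-by-cell by `shape_trace()`:

* single / average: conv 16×(3,1) preserving → 32×(3,1) valid (collapses
  the 3 electrode rows) → 32×(1,3) preserving → 64×(1,3) valid →
  flatten → dense 8 → dropout 0.5 → dense 4 softmax;
* two-person parallel: 16×(6,1) preserving, then channel collapses
  32×(3,1), 64×(3,1), 64×(2,1) taking 6→4→2→1, then 128×(1,3)
  preserving and 256×(1,3) valid;
* two-person serial: the single stack with tripled filters
  (48/96/96/192).

Conventions chosen where the tables are silent: batch normalization
after each convolution **before** ReLU (the conventional order); biases
on every convolution (redundant under batch norm but harmless);
"preserving" padding is symmetric zero-padding in the TensorFlow
`same` style (for even kernels the extra zero goes at the end); the
dense hidden layer of 8 units is **linear**, following the blank
activation cell in the printed tables; dropout (rate 0.5) sits only
between the two dense layers. For K > 2 parallel subjects the collapse
generalizes: a (3K,1) preserving input convolution, then (3,1) valid
collapses doubling filters from 32 (a final (2,1) if two rows remain,
repeating its predecessor's filter count), then the two frequency
convolutions at 2× and 4× the last collapse count — mirroring the
printed 6→4→2→1 pattern.

### The training engine

No deep-learning framework is available to R in this project's
dependency set, and the architectures themselves are the object of
study, so the package carries its own small engine: im2col convolution
as matrix products (hot kernels in C++ via RcppArmadillo), exact
backpropagation including the batch-norm recurrences, inverted dropout,
and Adam. Analytic gradients are verified against central-difference
numerical differentiation in the test suite (both inference and
training batch-norm paths). All stochasticity — initialization (He
normal), shuffling, dropout — flows from a single integer seed, so
training is bit-reproducible; this is asserted in the tests.

The cross-entropy loss uses the natural logarithm and clips
probabilities at 1e-12, since the loss is undefined at zero predicted
probability.

## Transfer-learning protocol

Stage one pretrains all layers with Adam at learning rate 0.001 for 80
epochs with mini-batches of 16. Stage two freezes the shallow half of
the convolution stack (rounded down: convs 1–2 of 4, or 1–3 of 6) and
fine-tunes the rest for 40 epochs. Decisions taken where the protocol is
underspecified:

* **Fine-tune learning rate 1e-4** — the protocol asks only for "a
  small" rate; one tenth of the pretraining rate is the documented,
  configurable default.
* **Freeze policy** — "shallow" is interpreted as the first half of the
  convolution stack; the policy is a named, configurable argument.
* **Frozen batch norm** — frozen layers run in inference mode during
  fine-tuning and their running statistics are pinned; otherwise the
  freezing contract (frozen tensors bit-identical before and after
  fine-tuning, asserted tensor-by-tensor) would be silently violated by
  forward-pass statistics updates.
* **Optimizer state is re-initialized** at the stage boundary.
* **Source-domain fusion pairings are random**, consistent with the
  observation that the choice of pretraining pairings does not affect
  the final classifier.

## Synthetic data model

The simulator exists so that every downstream stage is testable without
access to recordings. Each trial is

$$x_c(t) = A\Big[\alpha\, g_c \sum_{h=1}^{3} \tfrac1h
 \sin\big(2\pi h f (t-\tau) + h\varphi\big) + n_c(t)\Big],$$

with channel gains \(g = (0.9, 1.0, 0.9)\) (Oz dominant), harmonic decay
1/h and phase \(h\varphi\) (the standard SSVEP approximation), latency
\(\tau\), and background noise \(n_c\) that is 70% pink (1/f) and 30%
white by power, partially shared across channels (correlation 0.5
through a common source). The scale α is set per epoch so the realized
ratio of evoked power to noise power, summed over channels, equals the
configured SNR exactly; the subject's amplitude factor A then scales
the whole epoch, changing absolute amplitude but not SNR. Inter-subject
variability is limited to amplitude (log-normal, sd 0.2), an SNR offset
(Gaussian, sd 2 dB) and latency (Gaussian, sd 10 ms) — the minimal
model producing the individual differences that fusion is meant to
average out.

**SNR default.** Nothing in the protocol quantifies the recorded
subjects' signal quality, so the default was calibrated once, before any
test thresholds were pinned, so that the single-subject transfer
pipeline lands near the reported difficulty profile (about 90%
accuracy at 3 s degrading to the 60s at 1.6 s): `snr_db = -15`,
measured as total evoked power over total broadband noise power. High-SNR
checks use +15 to +20 dB, where the spectral peak is essentially always
identifiable.

What the simulator does **not** model: volume-conduction head geometry,
ocular/muscle artifacts, non-stationarity across a session, line noise,
or inter-subject differences in spectral shape. Passing tests therefore
demonstrate that the pipeline recovers structure the simulator puts in —
frequency-locked narrowband responses in broadband noise — not that it
attains any particular accuracy on real recordings.

## Evaluation workbench

Stratified shuffled k-fold cross-validation (every trial in exactly one
test fold; fold assignment seeded) with per-fold fine-tuning that always
restarts from one shared pretrained checkpoint never trained on target
data — preventing leakage across folds. The information transfer rate
uses the standard BCI formula with limits taken by continuity and floored
at zero; the selection time is the analysis window alone by default
(`include_rest_s` adds gaze-shift time for a conservative figure — which
of the two the original evaluation used is not stated, and its ITR values
are not printed, so no calibration is possible).

## Standard study designs and problem sizes

The packaged experiments (`run_single_tl_benchmark()`,
`run_fusion_benefit()`, `run_transfer_benefit()`) are the package's own
desk-scale designs, sized for a single CPU:

* high-SNR single-subject benchmark: 8 source subjects × 48 trials,
  one target subject, 10-fold cross-validation at 3 s;
* fusion benefit: 6 source subjects, two-subject target groups, windows
  {3.0, 2.2, 1.6} s (long/medium/short representatives of the 3.0–1.6 s
  sweep), 10 evaluation seeds per window, one pretraining per
  window/mode (the pretrained extractor is fixed infrastructure, as in
  the two-stage protocol; seeds vary the target groups), fine-tune on
  two thirds of 48 trials, test on the held-out third;
* transfer benefit: fine-tune on 24 target trials vs train from scratch
  on the same 24, tested on the other 24, over 10 paired seeds.

## Known limitations

* Accuracies reported on synthetic data characterize the implementation,
  not human subjects; the original recordings are not public, so the
  published accuracy table is a structural reference only.
* The serial-fusion 234-column discrepancy is documented, not resolved.
* The distributed (voting) cBCI variant and online/real-time operation
  are out of scope.
* The THU benchmark loader is a layout stub: the public corpus ships in
  a binary format this package does not parse.
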