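---
title: "Co-occurrence images for activity recognition: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-occurrence images for activity recognition: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(harimage)
```

This vignette is the package's account of its science: the model and its
assumptions, the parameters that matter, what the synthetic generator
does and does not emulate, and the numerical and design decisions taken
where more than one convention was defensible.

## The model

A tri-axial accelerometer worn in a trouser pocket measures gravity plus
body acceleration on three axes (X horizontal leg movement, Y vertical,
Z forward/backward) at a fixed rate f. Over a window of Δt seconds the
ν = Δt·f samples of two axes, plotted against each other, trace a cloud
whose shape is characteristic of the activity: a sitting person's cloud
is a tight dot displaced toward gravity-on-Z, a jogger's is an elongated
high-variance orbit in the (X, Y) plane. The package's feature — a
*HAR-Image* — makes that cloud explicit: for each of the
nC = q(q−1)/2 axis pairs, a 2D histogram of the ν (value-a, value-b)
pairs on a μ × μ grid over the global sensor range, counts capped at 255
and divided by 255. The three channels are stacked like the color
channels of an ordinary image and fed to a small convolutional network.

Two modelling assumptions are worth making explicit:

* **Stationarity within a window.** The histogram discards temporal
  order inside the window (the package tests this invariance
  explicitly), so the encoding assumes an activity's signature is the
  *distribution* of accelerations over 10 s, not their sequence. This is
  what distinguishes the approach from recurrent models.
* **A single label per window.** Windows are drawn inside maximal
  single-(user, activity) segments only, so every image has one ground
  truth. Activity transitions are therefore invisible to the classifier
  by construction.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| sampling rate f | 20 | Hz | one sample every 50 ms, the WISDM recording rate |
| window Δt | 10 (ν = 200 samples) | s | matches the feature window of the comparison datasets |
| stride | 10 | samples | dense overlap multiplies training data ~20× |
| sensor range | [−20, 20] | m/s² | the nominal output range of the phone accelerometer |
| bins μ | 40 | – | quantization step 0.025 of the normalized range; 40 × 40 channels |
| count cap | 255 | counts | 8-bit pixel convention; with ν = 200 ≤ 255 the cap is inactive |
| conv filters | 2, 4 of 2 × 2 | – | same padding, ReLU; two pooling stages 40 → 20 → 10 |
| dense layers | 48, 24 | neurons | dropout 0.5 after each |
| loss / optimizer | cross-entropy / Adam | – | sparse integer labels; Adam defaults (lr 1e-3, β₁ 0.9, β₂ 0.999, ε 1e-7) |
| epochs / batch | 100 / 5 | – | the stock training recipe; scale down for desk-scale runs |
| folds k | 10 | – | stratified per class |

## The quantization-step ambiguity

The stock configuration is stated both as a quantization step
Q = 0.025 and as 40 × 40 images, yet over the sensor range η = 40 m/s²
the relation μ = η/Q would give 1600 bins. The two statements are
consistent only if Q is read on the range normalized to [0, 1]
(μ = 1/Q = 40). The package makes the printed image size authoritative:
`quantization_spec()` takes a bin count (default 40), and
`bins_from_step()` honours μ = η/Q for users who have a step in raw
sensor units. Neither interpretation is silently blended.

A related choice: the quantization range is **global and fixed** rather
than per-window min/max. A per-window range would make bin width a
function of the window's own extremes, so identical acceleration pairs
would land in different cells depending on context, and the network
input geometry could vary. A fixed [−20, 20] range (configurable) keeps
images comparable and the CNN input constant.

## Numerical conventions

* **Bins** are half-open [edge, edge + w) with a *closed* top bin, so
  value_max falls in bin μ rather than an imaginary bin μ+1.
  Out-of-range values are clipped to the border bins by default
  (`clip_out_of_range = FALSE` turns them into errors instead).
* **Normalization** divides the capped counts by 255, not by the
  per-image maximum: the same count maps to the same intensity in every
  image, preserving cross-image comparability. With the default ν = 200
  the cap never binds and a channel's entries, times 255, sum exactly
  to ν (a tested conservation law).
* **Channel orientation**: the first axis of a pair indexes rows, the
  second columns; swapping a pair transposes the channel (tested).
  Channel order for three axes is (X,Y), (X,Z), (Y,Z).
* **Convolution** is implemented as cross-correlation (no kernel flip),
  the standard deep-learning convention and the one matching the index
  arithmetic K[p,q]·X[i+p−1, j+q−1]. "Same" padding at stride 1 with an
  even kernel needs asymmetric padding; the extra zero row/column goes
  bottom/right.
* **Pooling** drops trailing rows/columns that do not fill a block;
  with the default 40 → 20 → 10 chain nothing is ever dropped. Pooling
  ties keep the first (row-major) position for gradient routing.
* **Flattening** reads maps in filter order, each row-major — an
  arbitrary but fixed order shared by the reference operations and the
  compiled trainer, and covered by their equivalence test.
* **Softmax** subtracts the maximum logit before exponentiating;
  analytically a no-op, numerically what keeps large logits finite.
  Prediction takes the arg-max; exact ties resolve to the lowest class
  index.
* **Partial windows.** The window-count formula
  ⌈(D − ν)/stride + 1⌉ admits a final partial window when the stride
  does not divide D − ν. No padding policy is given for it anywhere, and
  padding would inject invented samples, so the extractor emits complete
  windows only; `window_count()` keeps the formula itself available, and
  the tested relation is: equal when stride | (D − ν), else one more
  than the emitted count.
* **Dropout** is active during training only (inverted dropout, so
  inference needs no rescaling). Weight initialization is Glorot
  uniform with an explicit seed; Adam hyperparameters beyond the name
  are the customary defaults, recorded in `training_config()`.

## The compiled trainer and its oracle

Training a CNN, even this small one, is not feasible in interpreted R
at tens of thousands of images, so the package carries a compiled
(RcppArmadillo) implementation of the forward and backward passes:
im2col + GEMM convolutions, max-pool argmax routing, dense layers, and
per-batch Adam updates. Correctness is anchored the other way round: the
exported pure-R operations (`conv2d_multichannel()`, `maxpool()`,
`flatten_concat()`, `dense_forward()`, `softmax()`) are direct,
loop-based transcriptions of the layer definitions; the test suite
checks the compiled first-layer output and the compiled full forward
pass against them to ~1e-10, and checks the R convolution itself against
an independent brute-force triple loop. Training is deterministic given
the seed: shuffling and dropout use one C++ RNG, weight initialization
uses R's RNG, and all are restored so callers' RNG state is untouched.

## Evaluation conventions

Per-class metrics come from the one-vs-rest reduction of the pooled
confusion matrix; the per-class accuracy (TP+TN)/total therefore counts
true negatives, the only reading under which a 6-class problem can show
per-class accuracies of ~0.999 alongside sensitivities of ~0.984. "AUC"
here is (sensitivity + specificity)/2 — balanced accuracy — not a
ROC-curve area; it is implemented as defined. Ratios with zero
denominators surface as NaN with a warning, never as silent zeros.
Rounding for table comparison is R's round-half-even to 3 decimals,
applied at the final step only.

Two conventions deserve flags:

* **Summary intervals.** For the across-class summary the package
  reports both mean ± sd and the normal-theory 95% interval
  mean ± 1.96·sd/√n; neither is canonical for a 6-value row and they
  are labelled separately rather than blended.
* **Fold assignment** is stratified per image. Because windows overlap
  (stride 10 within 200-sample windows), images from the same segment —
  sharing up to 95% of their samples — can land in different folds, so
  per-image cross-validation estimates are optimistic relative to a
  deployment on unseen users. This is the protocol the published results
  use, so it is the default; `cross_validate(..., folds = )` accepts any
  externally built assignment (e.g. grouped by user) when a stricter
  estimate is wanted.

## The synthetic generator

`synth_spec()` / `generate_dataset()` emulate the *structure* of the
WISDM raw data: multiple users, six activities, contiguous
per-(user, activity) segments, 20 Hz timestamps at exact 50 ms spacing,
values bounded in [−20, 20], written and re-read in the
`user,Activity,timestamp,x,y,z;` text dialect. Each activity is a
gravity vector plus sinusoids plus i.i.d. Gaussian noise: jogging a
high-amplitude ~2.5 Hz vertical oscillation, walking ~1.7 Hz at lower
amplitude, stairs walking-like with opposite-sign forward/backward
gravity bias and distinct vertical amplitude, sitting/standing static
with gravity mostly on Z or Y respectively. Profiles are validated
against the sensor bound (no systematic clipping) and Nyquist.

What the generator does **not** emulate: autocorrelated or heavy-tailed
sensor noise, gait variability within and across users (every user of a
class shares one deterministic signal shape), activity transitions
inside a segment, missing samples and timestamp jitter (jitter exists
only as an option), and the strong class imbalance of the real dataset
(the generator is balanced by design). Consequently, a model that is
perfect on the synthetic benchmark has demonstrated that the pipeline —
windowing, encoding, training, evaluation — is correct and that the
images separate distributionally distinct signals; it has *not*
demonstrated the published level of accuracy on real human data, which
is explicitly out of the package's offline scope. The bundled reference
confusion matrix of the published 10-fold run on the real dataset is
included precisely so the metric pipeline can be validated against
known real-data results.

## Problem sizes used by the test and acceptance runs

Desk-scale sizes, chosen as the package's own benchmark conditions: the
synthetic benchmark is 36 users × 6 activities × 60 s at 20 Hz, i.e.
259,200 samples and 21,816 images of 40 × 40 × 3, cross-validated with
k = 3 at 10 epochs and batch 32 (a scaled-down training recipe, labelled
as such; the stock recipe is 100 epochs at batch 5 with k = 10). Unit
and property tests run on windows of 4–200 samples and images of
8 × 8 × 3, where the brute-force oracles are exact and fast.

## Known limitations

* Single sensor only: the data model carries q ≥ 2 axes of one sensor;
  fusing several sensors' images (the general p > 1 tensor) is not
  implemented.
* The trainer supports the stock geometry (stride-1 same-padded
  convolutions); the reference operations additionally support valid
  padding and arbitrary strides.
* No GPU path, learning-rate schedules, or early stopping; the network
  is small enough that none are needed at these scales.
* The per-image fold default inherits the optimism of overlapping
  windows discussed above.
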