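---
title: "Grey-level probability labels, the expanded cross-entropy, and grey-mass evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grey-level probability labels, the expanded cross-entropy, and grey-mass evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greyunet)
```

## The problem and the idea

Breast lesions in B-mode ultrasound are hypoechoic, low-contrast regions with
blurred boundaries and strong speckle, and the clinically useful output is
not just *where* a lesion is but *what kind* it is: normal tissue, benign
tumour, or malignant tumour. `greyunet` implements a training scheme that
folds the three-class recognition into the segmentation target itself. The
three classes are encoded as a single grey scale — normal 0, benign 127.5,
malignant 255 on three equal channels — and, after division by 255, as
*grey-level probability labels* 0, 0.5 and 1. A U-Net trained against these
soft targets emits a greyscale map in which class identity is carried by
intensity, and texture inside the lesion survives because the target is not
forced to a hard binary plateau.

The normalization divisor is 255, not 256: only 255 maps the benign
three-channel grey 127.5 to exactly 0.5, which keeps the label table exact in
floating point. On disk, masks store the ordinary labels {0, 1, 2} in 8-bit
PNGs (127.5 is not representable in 8 bits); the 0.5 values exist only in
memory.

## The expanded cross-entropy and its fixed points

For a pixel with per-channel target $y^{(k)}$ and prediction $p^{(k)}$,
channels $k = 1,2,3$, the per-pixel entropy terms are
$E = \sum_k y^{(k)} \log p^{(k)}$ and
$E' = \sum_k (1-y^{(k)}) \log(1-p^{(k)})$, and the batch criterion is
$-\tfrac1N \sum_i (E_i + E'_i)$. Natural logarithms are used throughout
(the printed benign floor $-0.5\log\tfrac14 = \log 2 \approx 0.693$ is
base-agnostic as a symbol; natural log matches standard cross-entropy
practice). Within a batch element the channel sums are *averaged over
pixels*, so the loss magnitude is independent of image resolution; the sum
over batch elements is divided by $N$. Predictions are clipped to
$(10^{-7}, 1-10^{-7})$ before the logarithms.

Per channel the loss specializes to three cases, each with a closed-form
minimizer that the package also recovers by grid search at $10^{-6}$
resolution:

* $y = 1$: $\text{loss} = -\log p$, minimized as $p \to 1$;
* $y = 0.5$: $\text{loss} = -0.5\log[p(1-p)]$, minimized at $p = 0.5$ with
  minimum $\log 2$ — note this floor never reaches zero, and the case is
  symmetric under $p \leftrightarrow 1-p$;
* $y = 0$: $\text{loss} = -\log(1-p)$, minimized as $p \to 0$.

Because the channel sum runs over all three channels, the loss and its
gradient at identical per-channel $(y, p)$ are exactly three times the
single-channel binary cross-entropy. This is the "expanded" update-rate
property: the grey prediction moves three times faster per step without a
larger batch. The package asserts the factor for both loss values and
gradients over randomized draws.

## The softmax head and the grey reduction rate

The architecture's head is a softmax over the three channels, which
constrains $p_1 + p_2 + p_3 = 1$. Under that constraint the benign target
$(0.5, 0.5, 0.5)$ is unreachable; the reachable optimum of the benign
three-channel loss,

$$\min_{\;p_1+p_2+p_3=1}\; \sum_k -0.5\log[p_k(1-p_k)],$$

is $p = (1/3, 1/3, 1/3)$ (the objective is strictly convex on the open
simplex, so the symmetric point is the unique minimum;
`constrained_benign_minimum()` finds it numerically through a softmax
reparametrization and the test suite cross-checks it against a dense simplex
grid). With the display convention $\text{grey} = \text{mean}(p)\cdot 255$,
that optimum is grey $85$, i.e. a *grey reduction rate*
$\alpha = 85/127.5 = 2/3 \approx 0.667$ relative to the benign ground-truth
grey — exactly the observed benign output band around (80, 90).

The same analysis cuts the other way: under softmax, the malignant target
$(1,1,1)$ and the normal target $(0,0,0)$ are also unreachable, and *their*
constrained optima are likewise $(1/3,1/3,1/3)$. A softmax-headed network
trained with this loss therefore converges toward a flat grey-85 map — the
benign operating point is an analytic consequence of the head, but the
configuration cannot separate classes in the grey display. This tension is
left unresolved in the method as described; the package keeps softmax as the
default head (it is what defines $\alpha$) and offers
`unet_config(head = "sigmoid")`, under which all three targets are reachable
and the output map actually stratifies by class. Both the expanded loss
(`loss = "ece"`) and the per-channel binary cross-entropy it is compatible
with at deployment (`loss = "bce"`; same minimizer, one third the magnitude)
are available as training criteria, with ECE the default.

The display convention itself is a choice: nothing in the method fixes how
the 3-channel output becomes a grey map. The channel mean times 255 is used
because it is the only convention that places the softmax benign optimum
inside the printed benign band under equal channels.

## Architecture

Depth 4, base 8 feature channels doubling per level (8, 16, 32, 64, 128 at
the bottleneck), two 3×3 same-padding convolutions per level, 2×2 max-pool
down-sampling, 2×2 stride-2 transposed-convolution up-sampling, and skip
concatenation ("fusion") at each decoder level. "Normalization after each
convolution and deconvolution" is read as batch normalization (configurable
off); the leaky-ReLU negative slope is unstated in the method and defaults
to 0.01. The head is a 1×1 convolution from the 8-channel feature vector to
3 channels — base 8 is chosen precisely so the last decoder level emits 8
channels; the classic U-Net width (base 64) is a configuration away.

Seven dropout layers (rate 0.5) regularize training. The method counts seven
but a depth-4 U-Net has only four fusion layers, so the placement is a
declared design choice: one dropout after each of the four fusions, plus
after the two deepest encoder blocks and the bottleneck. At other depths the
same plan yields depth + 3 layers. Dropout is inverted (scaling by
$1/(1-P)$ at train time) and disabled at inference, so inference is
deterministic.

The engine behind the graph is a small vectorized CNN implementation:
feature maps are `(B·H·W) × C` matrices, 3×3 convolutions are im2col gathers
followed by BLAS matmuls, and every backward pass is hand-derived and
verified against central finite differences (layer-wise and through the
whole network) in the test suite. Weights use He initialization; the
optimizer is Adam (step size $10^{-3}$, $\beta = (0.9, 0.999)$) — the method
names no optimizer, and Adam is the field's default. Batch-norm running
statistics use momentum 0.9 with $\epsilon = 10^{-5}$.

## Grey-mass Dice and IOU

A greyscale output map with preserved texture cannot be scored fairly by
binary overlap. Instead, for each class the *grey masses* are compared: the
ground-truth mass $x_t$ (class pixel count × the Table grey, 127.5 or 255),
reduced by the class's grey reduction rate $\alpha$ (benign $2/3$,
malignant 1), against the predicted mass $x_p$ summed over the pixels of the
output map whose grey falls in the class band — benign $(80, 90)$, i.e.
$85 \pm \delta$ with $\delta = 5$; malignant $(170, 255]$, i.e.
$255 - \delta$ with $\delta = 85$. The bands are generated by $\alpha$ and
$\delta$; $\delta$ is interpreted as a per-pixel grey tolerance because that
reading reproduces both printed bands exactly. Band membership drives the
extraction; the signed difference $\Delta x = \alpha x_t - x_p$ is reported
alongside, and `within_tolerance` flags the per-pixel mean deviation
$\Delta x / n_t$ against $[-\delta, \delta]$ (benign) or $[0, \delta]$
(malignant).

The method's "geometric meaning" of Dice and IOU is operationalized on the
scalar masses as
$\text{Dice} = 2\min(\alpha x_t, x_p)/(\alpha x_t + x_p)$ and
$\text{IOU} = \min(\alpha x_t, x_p)/\max(\alpha x_t, x_p)$ — the unique
scalar analogue that preserves $\text{Dice} = 2\,\text{IOU}/(1+\text{IOU})$,
equals 1 exactly at $\alpha x_t = x_p$, is symmetric in the two masses, and
decreases monotonically as the predicted mass departs from the match. This
is an interpretation: whether the original per-image values used the min/max
form or a signed variant is not recoverable from the method's description.
On binary maps with $\alpha = 1$ and a full band, the grey-mass scores
reduce to classical mass-ratio scores; the classical set-overlap
coefficients are provided for comparison. Degenerate inputs are defined,
not crashed: a truth with no tumour scores 1 if the prediction is also
empty and 0 otherwise (with a warning), as do two empty masks under the
classical coefficients.

`render_expected_output()` renders a mask at the α-scaled operating greys
(benign 85, malignant 255). It — rather than the raw Table rendering at
127.5 — is the correct perfect-prediction reference, because a benign region
at grey 127.5 lies outside its own band by design.

## The phantom generator

The synthetic module stands in for clinical data so the pipeline is testable
end to end. Each phantom is a mid-grey (0.45) background carrying spatially
correlated multiplicative speckle (white noise smoothed by one 1-2-1 pass,
scaled to strength 0.15), with one hypoechoic lesion: benign lesions are
smooth rotated ellipses with boundaries blurred by two smoothing passes;
malignant lesions are radial polygons perturbed by low-order Fourier modes
(amplitudes up to 12% of the radius) with 2–4 bright internal spots —
mimicking the irregular margins and internal echogenic foci of malignant
masses. Defaults: 64 images at 64×64, lesion radii 8–16 px, benign fraction
0.885 (the 177:23 clinical class ratio). Per-image seeds make regeneration
bit-identical.

What the phantoms do **not** emulate: acoustic shadowing and enhancement,
depth-dependent attenuation and focus, a physical point-spread function,
operator variability, and the textural richness of real parenchyma. Passing
tests on phantoms therefore demonstrate the correctness and convergence of
the training/evaluation machinery, not clinical segmentation accuracy — the
clinical Dice/IOU figures of the original study are out of reach of any
desk-scale synthetic run, and the package makes no claim to reproduce them.

Geometric augmentation applies one sampled combination of horizontal and
vertical flips, rotation (±15°), translation (±10% per axis) and zoom
(0.9–1.1), identically to image and mask; the image is resampled bilinearly,
the mask by nearest neighbour so labels stay in {0, 1, 2}, and out-of-frame
coordinates are edge-clamped. The transform set and its ranges are a design
choice ("geometric transformation" being otherwise unspecified) and are
configurable. Flips, rotations and translations preserve the lesion pixel
count to within interpolation effects at the boundary (< 5% in the property
tests); zoom by construction scales the count by about the squared zoom
factor, so the < 5% preservation property is asserted for the
area-preserving subset only.

## Experiment sizes and numerical choices

The package's own experiments run at desk scale, chosen so the full
pipeline — generate, train, predict, evaluate — completes in minutes on one
CPU: 32 phantoms at 64×64, batch size 4, 12 epochs for the end-to-end run,
and 8–16 phantoms at 32×32 with shallow configurations for the unit-level
pipeline tests. At these sizes the training loss decreases monotonically and
the evaluation report is populated, which is what the end-to-end checks
assert; absolute epoch counts and absolute loss values from full-scale
clinical training are explicitly not asserted anywhere.

Remaining numerical conventions, in one place: probability clipping at
$10^{-7}$; grey histograms bin by `floor` into 256 bins; class bands are
open below and closed above so a saturated 255 output counts as malignant;
max-pool gradient ties break toward the first block element; mini-batch
order is reshuffled each epoch under the training seed; and every stochastic
component (weight init, shuffling, dropout, augmentation, phantom content)
is driven by explicit seeds, so training histories are reproducible
run-to-run.

## Known limitations

The CNN engine is CPU-only and sized for small experiments, not clinical
resolution. The softmax default head cannot produce class-separated grey
maps (see above) — that is a property of the method's stated configuration,
reproduced faithfully rather than repaired silently. The grey-mass
coefficients collapse each class to a scalar mass, so they measure intensity
calibration inside the band, not spatial coincidence; a spatially wrong
prediction with the right in-band mass scores well. Use the classical
coefficients alongside when spatial overlap matters.
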