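---
title: "A stochastic-pooling CNN pipeline for MS slice classification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stochastic-pooling CNN pipeline for MS slice classification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

msnet implements a complete image-classification pipeline for separating
2-D grayscale brain MRI slices of multiple-sclerosis (MS) patients from
healthy controls (HC): contrast normalization, a deterministic
five-transform augmentation scheme, a 14-layer convolutional network with
batch normalization, dropout and stochastic pooling, a repeated hold-out
evaluation harness, and an exact signed-rank test for comparing pooling
variants. This vignette records the model, its assumptions, and every
design decision that was genuinely open, so that a reader can judge what
the package's tests do and do not establish.

## Contrast normalization

Slices from different scanners arrive on different intensity scales.
Each image is histogram-stretched independently:

$$\varphi(x,y) = \frac{\mu(x,y) - \mu_{\min}}{\mu_{\max} - \mu_{\min}},$$

mapping every image onto $[0,1]$ with its minimum at 0 and maximum at 1.
The stretch is **per image** — the equation is written for a single image's
extrema — not per source pool. It is idempotent and invariant to positive
affine rescalings of the input, which is exactly the property that removes
a scanner's gain/offset signature. The degenerate case (a constant image)
has no defined stretch and raises an error rather than guessing.

Decoded integer images (8/16-bit PNG/TIFF, integer NIfTI) are divided by
the dtype maximum before stretching so the arithmetic is dtype-independent.

## Data augmentation

Five operators expand each training image into 150 derivatives:

| operator | grid / draw | count |
|---|---|---|
| rotation | $-30°$ to $30°$, step $2°$, $0°$ excluded | 30 |
| isotropic scaling | 0.7 to 1.3, step 0.02, 1.0 excluded | 30 |
| Gaussian noise | zero mean, variance 0.01, independent draws | 30 |
| translation | per-axis integer magnitude uniform on $[0,15]$ px | 30 |
| gamma correction | 0.4 to 1.6, step 0.04, 1.0 excluded | 30 |

The inclusive ranges contain 31 values each; the identity parameter is
excluded so that each deterministic grid contributes exactly 30 new
images and the total per image is 150 (a 151-fold training set). The
translation specification gives only a magnitude range; we draw the
magnitude and an independent random sign per axis, which is symmetric and
covers the stated range. Geometric transforms use bilinear interpolation
with zero fill (zeros match the MRI background); interpolation is
delegated to EBImage's affine warp. Noise is added after normalization —
a variance of 0.01 is only meaningful on a known intensity scale — and
clipped to $[0,1]$. Augmentation is applied to the training branch only,
never to test data.

## The network

The reference architecture counts 14 weight layers — 11 convolutional and
3 fully-connected; pooling, batch-norm, dropout and softmax are uncounted
sublayers, following the usual convention. All kernels are $3\times3$
with "same" padding. Output sizes follow

$$H_O = 1 + \left\lfloor \frac{2N + H_I - H_F}{M} \right\rfloor$$

for explicit padding $N$ and $\lceil H_I/M \rceil$ for same padding. Two
stride-2 convolutions and four stride-2 pooling stages reduce the input
by $2^6$, so a $256\times256$ slice ends at $4\times4\times64$ and the
first fully-connected layer consumes 1024 features. The working input
resolution is not part of the published layer tables; $256\times256$ is
the unique power-of-two side consistent with the 1024-unit flatten under
same padding, and `shape_trace()` verifies the chain for any configured
side rather than hard-coding it.

**Batch normalization** standardizes each conv channel over the
mini batch,

$$\tilde z = \gamma\,\frac{z - \alpha}{\sqrt{\sigma^2 + \varepsilon}} + \beta,$$

with population batch variance, $\varepsilon = 10^{-5}$ (we read the
customary framework default; the parameter is exposed for anyone
preferring $e^{-5} \approx 6.7\times10^{-3}$), learnable $\gamma,\beta$,
and running moments updated by exponential moving average (momentum 0.1)
for inference. Layer order is conv → batch norm → ReLU → (pool), the
standard placement; batch norm is attached to every conv layer and not to
the fully-connected layers. Freshly built networks start from running
moments (0, 1) so they are usable in inference mode before training.

**Stochastic pooling** operates on post-ReLU maps, so region activations
are non-negative. Training samples one activation per $3\times3$ region
from the multinomial $p_i = \chi_i / \sum_k \chi_k$; inference returns the
probability-weighted expectation $\sum_i p_i \chi_i$ (deterministic, the
convention of the method's origin — the published description covers
training only). All-zero regions output 0, with uniform probabilities as
the limiting convention. With same padding, padded positions are excluded
from max/average regions, average denominators and the multinomial sums:
zeros from padding would bias all three.

**Dropout** is inverted (survivors scaled by $1/(1-p)$ at training time),
so inference is the identity; the two fully-connected dropout layers use
$p = 0.5$.

**Training** is mini-batch SGD with momentum on the softmax cross-entropy.
The published account fixes only the schedule's shape — start large, cut
by a factor every fixed number of epochs — so the defaults (initial rate
0.01, factor 0.1 every 10 epochs, momentum 0.9, batch 128, 30 epochs) are
package choices, all exposed in `train_config()`. He-scaled Gaussian
initialization is used ("random" is all the source specifies; He scaling
is the ReLU-appropriate standard). A trailing mini batch of a single
image is dropped, since batch statistics need $m \ge 2$. MS is the
positive class throughout.

## Evaluation protocol

A single hold-out split (no validation set — dropout is the overfitting
control) with fixed per-class counts; the clinical protocol uses 350/350
training and 326/331 test images, exactly consuming a 676 MS + 681 HC
dataset. `multirun()` repeats the full protocol with fresh derived seeds
per run: new split, new augmentation draws, new initialization. Metrics
are reported as mean ± sample standard deviation (n−1), rounded to two
decimals only at display time. In a degenerate run whose classifier
predicts a single class, precision is undefined and recorded as `NA`
rather than aborting the experiment; `compute_metrics()` on its own stays
strict and raises an error.

## Exact signed-rank comparison of pooling variants

Per-run metrics of two pooling variants are paired by run. The test drops
zero differences, ranks absolute differences with average ranks for ties,
and computes the exact two-sided p-value by full enumeration of all
$2^n$ sign assignments **conditional on the observed (tied) rank vector**:
$p = \min(1, 2\,P(W \le \min(W^+, W^-)))$. Both conventions are forced by
the reference results: reproducing the published accuracy comparison of
stochastic vs max pooling requires the run-6 zero difference to be
dropped ($n_\text{eff} = 9$), and the specificity/sensitivity p-values
only emerge from the tied-rank conditional distribution. Metric vectors
rounded to two decimals routinely contain zeros and ties, which is also
why the normal approximation is avoided entirely. The enumeration is a
vectorized doubling of the attainable $W^-$ sums (literally the $2^n$
enumeration, laid out breadth-first) and is bounded at $n \le 20$ pairs;
comparisons of 10-run tables use $n \le 10$. Half-integer tied ranks are
compared with a $10^{-9}$ slack to absorb floating-point representation.

## The synthetic-data generator

No public accession exists for the clinical slices, so the package ships
a seeded generator of brain-slice-like phantoms: an elliptical "brain" of
smoothly textured tissue (low-pass-filtered Gaussian noise, correlation
length ~ side/16) over a dark background; the MS class adds 1–4
hyperintense Gaussian plaques (radius 3%–7% of the image side, contrast
0.35 above tissue) at uniform positions inside the ellipse; pixel noise
sd 0.02. Plaques are bright, matching the delineated hyperintense lesions
the clinical images show. The tissue texture amplitude (sd 0.06) is kept
well below the plaque contrast: lesions in delineated clinical slices are
conspicuous, several times the local texture variation, and a generator
whose texture peaks rival its lesions would be emulating a harder and
different task. The two classes are drawn through different "virtual
scanner" intensity scales, so the histogram-stretch stage performs a real
inter-source matching role on synthetic data too — training on
unnormalized phantoms lets a classifier read the class off the dynamic
range alone, and `normalize_dataset()` removes exactly that signature.
With plaque contrast 0 the two normalized class distributions coincide,
giving a null-calibration check (a trained classifier stays at chance).

What the generator does **not** emulate: anatomy (ventricles, cortical
folding), MRI physics (bias fields, partial-volume effects, Rician
noise), plaque shape irregularity, or any correlation between slices of
one subject. Passing tests on phantoms therefore demonstrate that the
pipeline's machinery is correct and that its stages play their intended
roles — not that the architecture reaches any particular accuracy on
clinical data.

## Problem sizes used by the test suite

The suite exercises training at reduced scale, chosen as the smallest
sizes at which each property is meaningfully testable: the end-to-end
sanity floor trains the reduced two-conv variant on 2,000 normalized
64×64 phantoms (700/700 train, 300/300 test) for 6 epochs and requires
≥ 95% test accuracy; the augmentation-stabilization property runs five
paired experiments on 32×32 phantoms (30/30 train, 50/50 test, 4 runs per
arm, 2 epochs) with a size-reduced augmentation grid (12 derivatives per
image) and requires the across-run accuracy SD to shrink under
augmentation in at least 4 of 5 pairs and on average; the
contrast-monotonicity trend uses three seeds × three contrast levels at
32×32. Monte-Carlo checks use $10^4$ draws for pooling frequencies and
200 random instances against a naive $2^n$ enumeration for the exact
test.

## Known limitations

* The training loop is plain R orchestrating Rcpp kernels; it is sized
  for the reduced experiments above, not for the full 105,700-image
  augmented clinical protocol on a single CPU.
* Stochastic-pooling inference uses the expectation rather than averaging
  many sampled passes; the two coincide only in expectation.
* The exact signed-rank enumeration is deliberately capped at 20 pairs;
  larger designs would need the shifted-convolution distribution, which
  this package intentionally omits (no approximate fallback is provided).
* The CLI reads whole directories into memory; datasets far larger than
  the clinical scale need chunked I/O that the package does not attempt.
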