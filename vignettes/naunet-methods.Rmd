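---
title: "Models and methods behind naunet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind naunet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The segmentation problem

Retinal vessel segmentation assigns every pixel of a color fundus photograph
a binary label: vessel or background. Vessel morphology is a diagnostic
signal for diabetic retinopathy, and the public DRIVE, HRF and CHASE_DB1
benchmarks provide expert-annotated ground truth for it. The networks in
this package are encoder-decoder convolutional models of the U-Net family:
a contracting path halves the spatial resolution five times while doubling
the channel width (the default schedule is 64, 128, 256, 512, 1024), and an
expanding path restores resolution while fusing encoder features back in
through skip connections.

## The neighbored-attention U-Net

NAU-Net modifies the skip pathway of the attention U-Net in two ways.

**Neighbored fusion.** At each level L of the encoder, the feature map of
the next-deeper level L+1 (with `2*ch` channels at half the resolution) is
up-convolved — x2 nearest-neighbor up-sampling, then a 3x3 convolution to
`ch` channels, batch normalization and ReLU — and concatenated with the
level-L map, giving a fused skip `e'_L` with `2*ch` channels. Only
neighboring levels are linked; there are no nested inner pathways as in
U-Net++, which is where the computational saving relative to U-Net++ comes
from.

**Attention gating.** Each of the four decoder levels carries an additive
attention gate over the pair (`e'_L`, `d_L`), where `d_L` is the
up-convolved decoder map:

    q_L     = ReLU(w_g e'_L + w_x d_L)
    alpha_L = sigmoid(w_alpha q_L)
    d'_L    = alpha_L * d_L        (elementwise, broadcast over channels)

`w_g`, `w_x` and `w_alpha` are 3x3 convolutions (stride 1), each followed by
batch normalization; `w_alpha` ends in a sigmoid, so every attention
coefficient lies strictly in (0, 1) and the gated map can only shrink. The
common intermediate width of `w_g` and `w_x` is half the decoder-side
channel count, the convention of the reference attention U-Net.

The decoder block at level L then consumes the concatenation
`[d'_L || e'_L]` (`3*ch` channels) and reduces it to `ch` channels with the
standard two-stage convolution block. A final 3x3 convolution maps the
64-channel output to one channel; a sigmoid yields the vessel probability
map. Output spatial dimensions always equal input dimensions, which is why
inputs must be divisible by 2^4.

### Design choices where the architecture was open

Several wiring details are not fully determined by the block descriptions
above; the package pins them as follows and exposes the relevant knobs in
`model_config()`:

* **Decoder wiring.** The gate output `d'_L = alpha_L * d_L` is concatenated
  with the fused skip `e'_L` before the decoder block (`3*ch` input
  channels). The alternative — re-projecting the fused skip to `ch` channels
  first — removes the extra width but adds a projection layer; the adopted
  form keeps the fused skip intact, which is the point of the fusion step.
  With the default schedule this wiring yields 48.64 M learnable parameters,
  between reported sizes of this architecture family; the published size of
  the original implementation (37.25 M) is not reproducible from the block
  descriptions alone — no wiring of the described components yields both
  that parameter count and the published FLOPs simultaneously (the two
  figures are mutually inconsistent for any gate whose width scales with the
  level), so the package documents its own accounting and reports what it
  builds.
* **Block ordering.** Convolution blocks use the conventional
  Conv -> BN -> ReLU ordering. The alternative ReLU-before-BN ordering has
  an identical parameter count and is available as
  `block_order = "conv_relu_bn"`.
* **Up-convolution.** "Up-convolution" is implemented as x2 nearest-neighbor
  up-sampling followed by a 3x3 convolution with stride and padding 1: a 2x2
  convolution with stride and padding 1 does not preserve the upsampled
  size, and the 3x3 form is what reproduces the attention U-Net baseline's
  published parameter count exactly.
* **Baselines.** The attention U-Net baseline uses its standard 1x1 gate
  convolutions and 1x1 output head; U-Net++ uses its original nested dense
  skip pathways with parameter-free up-sampling and a single (non-deeply-
  supervised) 1x1 head. Both choices reproduce the published sizes of those
  networks to the last parameter (34,878,573 and 36,629,633).
* **Initialization.** He-normal for convolution kernels, scale 1 / shift 0
  for batch normalization, seeded via `model_config(seed = )`.

## Loss and metrics

Training minimizes the compound BCE + soft-Dice loss. For predicted
probability maps `p_i` and binary masks `g_i` over a batch of N images:

    L = -(1/N) sum_i mean_pixels[ g_i log p_i + (1-g_i) log(1-p_i) ]
        + (1/N) sum_i [ 1 - 2 S_i / (2 S_i + FP_i + FN_i) ]

with soft counts `S_i = sum(p*g)`, `FP_i = sum(p*(1-g))`,
`FN_i = sum((1-p)*g)`. Two readings were fixed deliberately: the
cross-entropy weights log-probabilities of the prediction by the ground
truth (the printed form with the arguments transposed is undefined for
binary masks), and the Dice term uses the probabilistic relaxation, since
hard counts of a binarized prediction are not differentiable. Hard counts
are used only for evaluation. During training the loss is computed from
logits in the `log(1+exp(-|z|))` form, so no probability ever needs
clamping; the user-facing `bce_dice_loss()` clamps at 1e-7 and logs when it
does.

Evaluation binarizes the probability map at 0.5 (a choice, exposed as
`threshold`) and computes Dice, IoU, accuracy and precision from per-image
confusion counts. Metrics are computed per image and then averaged
(mean ± sample standard deviation), matching benchmark-table protocol; a
pixel-pooled variant sits behind `evaluate(pooled = TRUE)`. Conventions for
degenerate images are logged at use: Dice and IoU of two empty masks are 1;
precision without predicted positives is undefined and excluded from
summaries. Metrics run over all pixels of the resized image; no
field-of-view masking is applied by default.

## Training recipe

`train_config()` defaults encode the benchmark recipe: Adam, cosine
annealing `lr(t) = min_lr + (base_lr - min_lr)(1 + cos(pi t / T_max))/2`
with `T_max = 10` epochs (read as the cosine period, no restarts) and floor
`min_lr = 1e-4`, 140 epochs, batch size 4, inputs resized to 576 x 576 and
normalized with the ImageNet channel statistics. The base learning rate is
not part of the published recipe; the package defaults to the Adam
convention 1e-3. No augmentation is applied and no validation split or
early stopping exists by default; `val_samples` and `stop_dice` opt in.
Batch loss reduction is the mean, consistent with the 1/N in the loss.

## Complexity accounting

The profiler walks the model's instruction program over shapes, so
profiling a 576 x 576 input allocates no tensors. Counting rules:

| layer | FLOPs | MAdds |
|---|---|---|
| convolution (k, stride 1, bias) | `k^2 c_in c_out H W` (MACs) | `2 MACs` |
| batch normalization | 2 / element | same |
| ReLU, up-sample, add, gate multiply | 1 / element | same |
| sigmoid | 4 / element | same |
| 2x2 max pool | 4 / output element | same |

For convolutions the MAdds rule is `2 MACs - c_out H W` plus `c_out H W`
bias adds, which collapses to `2 MACs`. Memory is 4 bytes per activation
element summed over the input and every instruction's output at batch size
1, plus 4 bytes per parameter; optimizer state is excluded. These
conventions reproduce the published attention U-Net figure (337.26 G FLOPs
at 3x576x576) to 0.03% and the published orderings across all three models;
non-convolution rules in the profiling tool that produced the published
table are undocumented, which is why FLOPs carry a tolerance while
parameter counts are exact.

## Synthetic fundus data

`generate_synthetic_fundus()` renders what a vessel-segmentation pipeline
actually consumes: a circular field of view on a dark border, a smoothly
textured reddish background (coarse Gaussian grid, bilinearly upsampled),
and `n_trees` recursively branching dark curves rendered as stamped discs
along jittered-heading walks, with child width decaying by `width_decay`
per generation. The mask is exactly the set of rendered vessel pixels
clipped to the field of view, and images are quantized to the 8-bit grid at
generation time so a PNG write/read round trip is bit-exact. Default
conditions (size 128, 4 trees, depth 4, root width 3 px, decay 0.8, vessel
level 70 on background 170, noise sd 8) give vessel fractions around
0.06-0.14 of the field of view — the band real fundus images occupy — and a
high-contrast, low-noise task a small network can learn quickly.

What the generator does *not* emulate: central vessel reflex, the bright
optic disc and macula, lesions, contrast drift toward the FOV rim, and
annotator noise. Passing the synthetic end-to-end test therefore
demonstrates that the architecture, gradients, loss, scheduler and metrics
work together — not that benchmark-level accuracy transfers to real fundus
data, which requires the real datasets and full-scale training.

The end-to-end learnability check trains the reduced schedule
(8, 16, 32, 64, 128) on 64 synthetic 128 x 128 images with batch size 4 for
at most 30 epochs and requires held-out Dice above 0.85; with the default
seeds it converges in about 3 epochs. Problem sizes in the test suite
(tiny schedules, 32-128 px inputs) were chosen so the full suite runs in a
few minutes on one CPU core.

## Numerical notes and limitations

* Batch normalization uses eps 1e-5 and momentum 0.1 on running statistics;
  training mode normalizes by biased batch variance, evaluation by the
  unbiased running estimate.
* Convolution biases that feed directly into a batch normalization have
  exactly zero gradient (the normalization absorbs any constant shift);
  they are retained for parameter-count parity with the reference
  implementations.
* The gradient tape frees intermediate gradients as it walks backward;
  peak training memory is roughly two activations per layer.
* Max pooling breaks ties toward the first (top-left) element; tied maxima
  route all gradient to that element.
* All computation is double precision on CPU. Results are reproducible on
  one machine but, as with any floating-point training, not guaranteed
  bit-identical across BLAS builds.
* DRIVE distributes manual masks as GIF, which no installed reader
  supports; the loader accepts the same basenames in PNG/TIFF and raises a
  conversion hint on GIF files.
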