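---
title: "Methods: lesion-aware triple-path feature fusion segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lesion-aware triple-path feature fusion segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`ltpnet` segments a single lesion from a dermoscopy image with an
encoder–decoder network organized in three stages.

**Extraction.** A five-level hierarchical encoder produces features at
strides 4, 8, 16, 32 and 64 relative to the input (`H_i = H / 2^(i+1)`).
The published architecture uses a hybrid mobile state-space backbone whose
internals are not public; this package substitutes a configurable
stage-wise convolutional encoder (a stride-4 stem and four stride-2
stages, each optionally ending in a selective-scan residual block) behind
the same five-level contract, so a faithful backbone port can be dropped in
behind `extract_pyramid()` without touching the decoder.  At every scale,
foreground–background attention re-weights the feature and adds it back:
`f'_i = SA(CA(f_i)) ⊕ f_i`.  The channel gate is an SE block; the spatial
gate pools channel-wise max and mean maps through a 7×7 convolution and a
sigmoid.  Both return re-weighted features (the alternative reading — raw
attention maps — does not compose with the residual addition).

**Refinement.** The decoder alternates two refinement blocks.  The
attentive spatial modulator (ASM) wraps a parallel local/global core
between two depthwise-separable-convolution + feedforward residual
sandwiches and finishes with bilinear 2× upsampling.  The local branch
(residual gated attention) multiplies two conv–groupnorm–ReLU transforms
elementwise, refines the product with a third and adds the input back.  The
global branch (SS2D) unfolds the map along four scan paths (row-major and
column-major, each in both orders), runs an input-dependent linear
state-space recurrence along each sequence, folds the four outputs back and
sums them.  Lesion-aware lite-gate attention (LALGA) then recalibrates
channels: an asymmetric spatial gate (one bottleneck block multiplied by a
cascade of two) followed by global-average-pooling-driven channel
reweighting, wrapped in a channel-preserving bottleneck residual.

**Aggregation.** Triple-path feature fusion (TPFF) merges the lateral
refined feature with the decoded feature from the level above through three
pathways — addition (common), multiplication (saliency), subtraction
(difference) — each refined by channel attention.  The residual convention
differs deliberately between paths: the common path adds its own sum back,
while saliency and difference add the *low-level* input.  The pathway
outputs are combined with learnable coefficients `(α, β, γ)` held on the
probability simplex.

One full forward pass applies ASM five times, LALGA eight times and TPFF
four times; the test-suite asserts these invocation counts, the extent
match at every fusion junction, and bitwise inference determinism.

## Decisions taken where the design was open

* **Simplex constraint.** The source material states both fixed values
  (0.4, 0.2, 0.4) and "learnable" for the fusion coefficients.  We make
  them learnable as a softmax over three logits initialized at
  `log(0.4, 0.2, 0.4)`, which reproduces the stated starting point exactly,
  keeps all three coefficients strictly positive, and makes `α+β+γ = 1`
  hold to machine epsilon after every optimizer step.  Coefficients are
  per-decoder-level, not shared.  When a pathway is ablated its coefficient
  mass is renormalized over the active paths.
* **Channel plumbing.** The equations never state how the channel count
  changes across decoder levels.  ASM at level *i+1* therefore ends in a
  1×1 projection to the level-*i* width (placed after the upsample), which
  is the minimal operator making the elementwise TPFF fusions well-typed.
  The ordering question at the top of the decoder (whether the high-level
  TPFF input passes ASM before LALGA) is resolved the only way the four
  dataflow equations compose: ASM, then LALGA, then TPFF.
* **Bottleneck structure.** "Bottleneck convolution" is realized as 1×1
  reduce (ratio 4) → 3×3 → 1×1 expand, then group norm and ReLU.  The ratio
  is clamped to the input channel count; an explicit ratio larger than the
  channel count is a configuration error.
* **Segmentation head.** Unspecified upstream; after the last ASM the map
  sits at input/2, so the head is bilinear 2× upsampling, a 1×1 convolution
  to one channel, and a sigmoid.  Binarization uses threshold 0.5 with the
  documented tie rule *positive iff probability ≥ threshold*.
* **mIoU definition.** The printed (DSC, mIoU) headline pairs satisfy
  `IoU = DSC/(2−DSC)` to the last digit, which holds exactly only for a
  single aggregated confusion matrix over the lesion class.  The package
  therefore reports foreground IoU on dataset-aggregated pixel counts and
  asserts the identity as a property test; per-image Dice values are also
  emitted for dispersion.

## The selective scan, concretely

Per direction the recurrence is `h_t = exp(Δ_t A) h_{t-1} + Δ_t B_t x_t`,
`y_t = C_t · h_t + D x_t` with `A = −exp(logA)` (per state and channel, so
the discretized decay lies in (0,1)), `Δ_t = softplus(W_Δ x_t + b_Δ)` per
channel, `B_t, C_t` linear projections of the position's feature shared
across channels, and a per-channel skip gain `D`.  Initialization follows
standard state-space practice: `A_n = −n`, `softplus(b_Δ) ≈ 0.05`, small
random projections, `D = 1`.  The scan is implemented as an explicit
sequential loop (state dimension 16 by default, 8 in the tiny preset) —
numerically transparent and oracle-checkable; the test-suite compares it
elementwise against a naive per-timestep R recurrence and validates the
hand-derived backward pass against central finite differences.

## Training protocol

AdamW (initial learning rate 1e-3, decoupled weight decay 1e-2) under a
cosine schedule fixed before training starts
(`lr(t) = lr_min + (lr0−lr_min)(1+cos(πt/T))/2`); images resized
bilinearly, masks by nearest neighbor (preserving the label set exactly);
augmentation restricted to flips and right-angle rotations, which are
lattice bijections and hence preserve mask areas exactly; hybrid loss
`λ₁·BCE + λ₂·Dice` with `λ₁ = λ₂ = 1`.  Per-channel normalization
statistics are computed from the training split and stored in the
checkpoint.  Reference batch size and resolution (32 at 256×256) are
GPU-scale settings; the `tiny` preset (64×64 inputs, channels
8/16/24/32/48, state dimension 8, full batch of 8) is the CPU-scale
configuration used by the tests.

## Numerical choices

* Dice smoothing and BCE clamping use `ε = 1e-7`; the loss is exactly
  additive in its two terms and nonnegative.
* Group-norm groups default to 8 and are clamped per layer to the largest
  divisor of the channel count; `ε = 1e-5`.
* Convolutions are Kaiming-initialized with zero biases and
  identity-affine normalizations, so the zero-input collapse identities in
  the tests hold exactly, not approximately.
* The SE/GGCA squeeze MLPs keep at least four hidden units regardless of
  the reduction ratio: at desk-scale channel widths a one-unit ReLU
  bottleneck is dead at initialization with probability ~1/2, which
  permanently stalls the gate.  With the floor, a fully dead squeeze is
  rare but not impossible (~0.5⁴ per gate per initialization); the
  gradient-flow test fixes a seed at which every parameter is reachable.
* The deepest level of a 64×64 input is a 1×1 map, a one-step scan: the
  decay parameters of that level's scan receive structurally zero gradient
  (there is no previous state to decay).  Gradient-flow is therefore
  asserted at 128×128, where every parameter participates.
* Bilinear resizing uses the half-pixel-center convention; channel-max
  pooling breaks ties toward the first maximal channel.
* Probabilities, not logits, cross the loss boundary; the clamped BCE
  gradient is exact on the clamp interior.

## The synthetic stated world

Each generated image is a skin-tone background (tan palette with per-image
jitter and smooth low-frequency texture) containing one star-convex lesion:
an ellipse whose boundary radius is modulated by random harmonics
`r(θ) = 1 + Σ_{k=2..6} a_k cos(kθ + φ_k)` with `|a_k| ≤ 0.25`, guaranteeing
a single 4-connected component.  The lesion is darkened in proportion to
the `contrast` parameter, alpha-blended with a Gaussian-blurred boundary
(`boundary_blur_sigma`), overlaid with dark Bézier hair strokes drawn
*after* compositing (excluded from the mask, matching ground-truth
semantics of public dermoscopy datasets), and perturbed with Gaussian pixel
noise.  The mask is the exact pre-blur region; coverage is held inside
`lesion_area_fraction` (default 8–35%) by bounded rejection.  Three regimes
mirror the classic challenge taxonomy: `complex` (6 hairs, sharp boundary),
`blurred` (σ = 3 boundary), `lowcontrast` (contrast 0.15).

What a green test establishes: the implementation is internally consistent
(oracle equivalence), trainable (the tiny preset overfits 8 images to
Dice ≥ 0.95 inside 300 steps), and its generator's knobs move the intended
statistics in the intended directions.  What it does not establish:
performance on real dermoscopy data — the generator has no ruler or gel
artifacts, no multi-lesion images, no camera noise model, and its lesion
appearance is far simpler than real pigment networks.  Published benchmark
numbers require the external datasets and GPU-scale training and are out of
scope here.

## Engineering notes

No deep-learning runtime exists for R in the supported environment, so the
package carries a small reverse-mode autodiff engine (creation-ordered tape
over rank-4 arrays) with compiled C++ kernels for the three hot primitives:
dense convolution (im2col + BLAS), group normalization, and the selective
scan with its hand-derived backward.  Every primitive's gradient is checked
against central finite differences.  PNG I/O is likewise self-contained
(8-bit grayscale/RGB, all five scanline filters on read), built on R's zlib
bindings, and was validated against an independent reference reader during
development.  Configuration surfaces are R constructors and
JSON-serializable lists; no YAML parser is available in the environment.

## Known limitations

* CPU-only; the `paper`-preset resolution trains impractically slowly
  without batching across processes.
* The encoder is a stand-in with the correct contract, not a port of the
  published backbone; headline benchmark numbers are not reproducible here.
* Batch normalization inside ASM's DB blocks uses batch statistics during
  training and running statistics at evaluation; with tiny batches the two
  can differ early in training.
* The PR curve uses linear (trapezoidal) interpolation between operating
  points, which slightly flatters PR-AUC where precision is volatile.
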