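# ltpnet

Lesion-aware triple-path feature fusion networks for skin-lesion
segmentation, implemented end-to-end in R.

## What this package is for

Automated delineation of pigmented lesions in dermoscopy images is hard in
exactly three situations: cluttered backgrounds (hair, illumination),
blurred lesion boundaries, and low lesion-to-skin contrast.  `ltpnet`
implements an encoder–decoder segmentation architecture designed around
those failure modes and makes every stage available as a tested, composable
module:

* **FBA** (foreground–background attention) — at every encoder scale,
  sequential channel attention (SE) and spatial attention with a residual
  add: `f' = SA(CA(f)) ⊕ f`.
* **ASM** (attentive spatial modulator) — a decoder refinement block:
  `f1 = FFN(DB(f)) + f`, `f2 = (SS2D(f1) + RGA(f1)) + f1`,
  `f3 = FFN(DB(f2)) + f2`, then bilinear 2× upsampling.  RGA is residual
  gated attention (`CGR(CGR(f) ⊗ CGR(f)) + f`); SS2D is a four-direction
  2-D selective scan, an input-dependent linear state-space recurrence
  `h_t = exp(Δ_t A) h_{t-1} + Δ_t B_t x_t`, `y_t = C_t·h_t + D x_t` run over
  row-major and column-major unfoldings in both orders.
* **LALGA** (lesion-aware lite-gate attention) —
  `y = BGR(GGCA(LAGA(x)) + x)`, where LAGA multiplies an asymmetric pair of
  bottleneck branches (`BGR(x) ⊗ BGR(BGR(x))`) and GGCA recalibrates
  channels with `w = σ(Conv(ReLU(Conv(GAP(·)))))`.
* **TPFF** (triple-path feature fusion) — cross-scale fusion
  `αCP + βSP + γDP` with a common (add), saliency (multiply) and difference
  (subtract) path, each refined by channel attention, and learnable
  coefficients constrained to the simplex by a softmax, initialized at
  exactly `(α, β, γ) = (0.4, 0.2, 0.4)`.
* **Loss / metrics** — hybrid `λ₁·BCE + λ₂·Dice` loss (`λ₁ = λ₂ = 1`),
  dataset-aggregated mIoU, DSC, accuracy, specificity, sensitivity
  (`mIoU = DSC/(2−DSC)` on a single confusion matrix), and PR/ROC curves
  with trapezoidal AUCs.
* **Synthetic data** — a procedural generator of dermoscopy-like image/mask
  pairs (skin-tone background, one star-convex lesion, controllable
  boundary blur, contrast and hair occlusion) so the whole pipeline is
  testable without downloads.

Because no deep-learning runtime is available for R in the target
environment, the package ships its own small reverse-mode automatic
differentiation engine; the heavy primitives (dense convolution, group
normalization, the selective scan) run as compiled C++ kernels and every
backward pass is validated against finite differences in the test-suite.

## Worked example

```r
library(ltpnet)
set.seed(1)

# 1. synthesize a tiny training set (8 dermoscopy-like images, 64x64)
pairs <- lapply(1:8, function(i) generate_lesion_image(synth_params(seed = i)))
mean(pairs[[1]]$mask)              # lesion covers 24.0% of the first image

# 2. build the tiny-preset network and overfit it on the 8 images
model <- ltpnet(ltpnet_config("tiny"), seed = 7)
module_n_params(model)             # 322644 trainable scalars
hist <- train_ltpnet(model, pairs,
                     train_config(batch_size = 8, steps = 150,
                                  augment = FALSE, seed = 7))
c(hist$loss[1], hist$loss[150])    # 3.862 -> 0.098

# 3. evaluate on the training images
ev <- evaluate_ltpnet(model, pairs)
round(unlist(ev$metrics), 4)
#>     acc     sen     spe     dsc    miou  auc_pr auc_roc
#>  0.9848  0.9645  0.9912  0.9679  0.9379  0.9952  0.9984

# 4. the fusion coefficients stay on the simplex while they adapt
round(tpff_coefficients(model$tpffs$tpff1), 4)
#>  alpha   beta  gamma
#> 0.4210 0.1922 0.3869
```

The Dice of 0.968 against exact ground truth confirms the architecture's
learnability at desk scale: the hybrid loss falls monotonically from the
first step and the network reconstructs the lesion masks it was shown.
`hist$coeff_sum` is identically 1 — the TPFF simplex constraint holds after
every optimizer step.

## Command line

```sh
Rscript inst/cli/ltpnet synth --n 8 --out data/demo --seed 1
Rscript inst/cli/ltpnet train --data data/demo --out runs/demo --steps 150 --batch 8
Rscript inst/cli/ltpnet eval  --checkpoint runs/demo/checkpoint.rds --data data/demo --out runs/demo
Rscript inst/cli/ltpnet predict --checkpoint runs/demo/checkpoint.rds --data data/demo --out runs/demo/preds
```

## Layout

* `R/` — autodiff engine, layers, the five architecture modules, losses and
  metrics, synthetic generator, data pipeline, training loop, CLI.
* `src/` — C++ kernels (convolution, group norm, selective scan).
* `tests/testthat/` — unit, property and acceptance suites; independent
  oracles (direct-loop convolution/normalization/scan, O(n²) AUC, finite
  differences) live in `helper-ltpnet.R`.
* `vignettes/` — methods vignette describing the model, the numerical
  choices and the limits of what the synthetic benchmark establishes.
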