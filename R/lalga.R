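# Lesion-aware lite-gate attention (LALGA): an asymmetric dual-path spatial
# gate (LAGA: one BGR in the shallow path, two cascaded BGRs in the deep
# path, fused multiplicatively) followed by global-guided channel
# recalibration (GGCA), wrapped in a channel-preserving BGR residual:
#     y = BGR(GGCA(LAGA(x)) + x).

#' Create a lightweight asymmetric gating attention (LAGA) block
#'
#' `g1 = BGR(x)` (shallow), `g2 = BGR(BGR(x))` (deep);
#' `fgate = g1 * g2` elementwise.  The output is nonnegative because both
#' branches end in a ReLU.
#'
#' @param C channel count (preserved).
#' @param bottleneck_ratio,gn_groups BGR hyperparameters.
#' @return a module; apply with [laga()].
#' @export
new_laga <- function(C, bottleneck_ratio = 4L, gn_groups = 8L) {
  cfg <- block_config(C, C, bottleneck_ratio = min(bottleneck_ratio, C),
                      gn_groups = gn_groups)
  shallow <- new_bgr(cfg)
  deep1 <- new_bgr(cfg)
  deep2 <- new_bgr(cfg)
  m <- new_module("laga", children = list(shallow = shallow,
                                          deep1 = deep1, deep2 = deep2))
  m$forward <- function(x) {
    x <- as_tn(x)
    t_mul(shallow$forward(x), deep2$forward(deep1$forward(x)))
  }
  m
}

#' Apply LAGA
#' @param mod module from [new_laga()].
#' @param f feature tensor/array.
#' @return elementwise-nonnegative tensor with the extents of `f`.
#' @export
laga <- function(mod, f) mod$forward(as_tn(f))

#' Create a global-guided channel attention (GGCA) block
#'
#' `w = sigmoid(Conv(ReLU(Conv(GAP(fgate)))))`, applied as a per-channel
#' scale broadcast over space.  Weights are strictly in (0, 1).
#'
#' @param C channel count.
#' @param reduction squeeze ratio between the two 1x1 convolutions.
#' @return a module; apply with [ggca()].
#' @export
new_ggca <- function(C, reduction = 4L) {
  hidden <- max(min(4L, C), C %/% reduction)  # keep >= 4 squeeze units alive
  fc1 <- new_conv(C, hidden, k = 1L)
  fc2 <- new_conv(hidden, C, k = 1L)
  m <- new_module("ggca", children = list(fc1 = fc1, fc2 = fc2))
  m$weights <- function(x) {
    t_sigmoid(fc2$forward(t_relu(fc1$forward(t_gap(as_tn(x))))))
  }
  m$forward <- function(x) {
    x <- as_tn(x)
    t_mul(x, m$weights(x))
  }
  m
}

#' Apply GGCA
#' @param mod module from [new_ggca()].
#' @param f feature tensor/array.
#' @return `f` rescaled by spatially uniform per-channel weights in (0, 1).
#' @export
ggca <- function(mod, f) mod$forward(as_tn(f))

#' Create a lesion-aware lite-gate attention (LALGA) block
#'
#' `y = BGR(GGCA(LAGA(x)) + x)`; channel-preserving.
#'
#' @param C channel count.
#' @param ggca_reduction GGCA squeeze ratio.
#' @param bottleneck_ratio,gn_groups BGR hyperparameters.
#' @return a module; apply with [lalga_forward()].
#' @export
new_lalga <- function(C, ggca_reduction = 4L, bottleneck_ratio = 4L,
                      gn_groups = 8L) {
  lg <- new_laga(C, bottleneck_ratio, gn_groups)
  gg <- new_ggca(C, ggca_reduction)
  out_bgr <- new_bgr(block_config(C, C, bottleneck_ratio = min(bottleneck_ratio, C),
                                  gn_groups = gn_groups))
  m <- new_module("lalga", children = list(laga = lg, ggca = gg, out_bgr = out_bgr))
  m$forward <- function(x) {
    x <- as_tn(x)
    out_bgr$forward(t_add(gg$forward(lg$forward(x)), x))
  }
  m
}

#' Apply LALGA
#' @param mod module from [new_lalga()].
#' @param f feature tensor/array.
#' @return elementwise-nonnegative tensor with the extents of `f`.
#' @export
lalga_forward <- function(mod, f) mod$forward(as_tn(f))
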