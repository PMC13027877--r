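# Attentive spatial modulator (ASM): a DB/FFN residual sandwich around a
# parallel residual-gated-attention + 2D-selective-scan core, followed by
# bilinear 2x upsampling and a 1x1 channel projection to the next decoder
# level's width.

# DB: 3x3 depthwise separable convolution (depthwise then pointwise) with
# batch normalization.
new_db <- function(C) {
  dw <- new_dwconv(C, 3L)
  pw <- new_conv(C, C, k = 1L)
  bn <- new_batchnorm(C)
  m <- new_module("db", children = list(dw = dw, pw = pw, bn = bn))
  m$forward <- function(x) bn$forward(pw$forward(dw$forward(x)))
  m
}

# FFN: 1x1 expand -> GELU -> 1x1 reduce (transformer-style feedforward).
new_ffn <- function(C, expansion = 4L) {
  up <- new_conv(C, C * expansion, k = 1L)
  down <- new_conv(C * expansion, C, k = 1L)
  m <- new_module("ffn", children = list(up = up, down = down))
  m$forward <- function(x) down$forward(t_gelu(up$forward(x)))
  m
}

#' Create a residual gated attention (RGA) block
#'
#' Two parallel CGR branches multiplied elementwise, refined by a third CGR,
#' with a residual shortcut: `RGA(f) = CGR(CGR(f) * CGR(f)) + f`.
#'
#' @param C channel count.
#' @param gn_groups requested group-norm groups.
#' @return a module; apply with [rga()].
#' @export
new_rga <- function(C, gn_groups = 8L) {
  cfg <- block_config(C, C, gn_groups = gn_groups)
  a <- new_cgr(cfg); b <- new_cgr(cfg); refine <- new_cgr(cfg)
  m <- new_module("rga", children = list(branch_a = a, branch_b = b, refine = refine))
  m$forward <- function(x) {
    x <- as_tn(x)
    t_add(refine$forward(t_mul(a$forward(x), b$forward(x))), x)
  }
  m
}

#' Apply residual gated attention
#' @param mod module from [new_rga()].
#' @param f feature tensor/array.
#' @return tensor with the extents of `f`.
#' @export
rga <- function(mod, f) mod$forward(as_tn(f))

#' Create the parallel RGA + SS2D unit
#' @param C channel count.
#' @param state_dim selective-scan state dimension.
#' @param gn_groups requested group-norm groups.
#' @return a module with children `rga` and `ss2d`; apply with [rga_ss2d()].
#' @export
new_rga_ss2d <- function(C, state_dim = 16L, gn_groups = 8L) {
  r <- new_rga(C, gn_groups)
  s <- new_ss2d(C, state_dim)
  m <- new_module("rga_ss2d", children = list(rga = r, ss2d = s))
  m$forward <- function(x) {
    x <- as_tn(x)
    t_add(s$forward(x), r$forward(x))
  }
  m
}

#' Apply the parallel RGA + SS2D unit (elementwise sum of both branches)
#' @param mod module from [new_rga_ss2d()].
#' @param f feature tensor/array.
#' @return tensor with the extents of `f`.
#' @export
rga_ss2d <- function(mod, f) mod$forward(as_tn(f))

#' Create an attentive spatial modulator (ASM)
#'
#' Computes `f1 = FFN(DB(f)) + f`, `f2 = (SS2D(f1) + RGA(f1)) + f1`,
#' `f3 = FFN(DB(f2)) + f2`, then bilinear 2x upsampling and a 1x1 projection
#' from `channels_in` to `target_channels`.
#'
#' @param channels_in input channel count.
#' @param target_channels output channel count after projection.
#' @param state_dim selective-scan state dimension.
#' @param ffn_expansion FFN expansion factor.
#' @param gn_groups requested group-norm groups.
#' @param core_enabled when `FALSE` (ablation), the refinement sandwich is
#'   replaced by the identity; upsampling and projection are retained so the
#'   decoder dataflow still type-checks.
#' @return a module; apply with [asm_forward()].
#' @export
new_asm <- function(channels_in, target_channels = channels_in,
                    state_dim = 16L, ffn_expansion = 4L, gn_groups = 8L,
                    core_enabled = TRUE) {
  ch <- list(proj = new_conv(channels_in, target_channels, k = 1L))
  if (core_enabled) {
    ch <- c(list(db1 = new_db(channels_in), ffn1 = new_ffn(channels_in, ffn_expansion),
                 core = new_rga_ss2d(channels_in, state_dim, gn_groups),
                 db2 = new_db(channels_in), ffn2 = new_ffn(channels_in, ffn_expansion)),
            ch)
  }
  m <- new_module("asm", children = ch)
  m$core_enabled <- core_enabled
  m$forward <- function(x) {
    x <- as_tn(x)
    f3 <- if (core_enabled) {
      f1 <- t_add(ch$ffn1$forward(ch$db1$forward(x)), x)
      f2 <- t_add(ch$core$forward(f1), f1)
      t_add(ch$ffn2$forward(ch$db2$forward(f2)), f2)
    } else x
    ch$proj$forward(t_upsample_bilinear(f3, 2L))
  }
  m
}

#' Apply an attentive spatial modulator
#' @param mod module from [new_asm()].
#' @param f feature tensor/array (batch, channels_in, H, W).
#' @return tensor (batch, target_channels, 2H, 2W).
#' @export
asm_forward <- function(mod, f) mod$forward(as_tn(f))
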