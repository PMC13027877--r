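# Shared parameterized operators: CGR (conv + group norm + ReLU), BGR
# (bottleneck conv + group norm + ReLU) and SE-style channel attention.
# Every other module composes these.

#' Block configuration
#'
#' Hyperparameters shared by the elementary blocks.
#'
#' @param channels_in,channels_out channel counts.
#' @param bottleneck_ratio reduction factor of the BGR bottleneck (the 3x3
#'   core runs at `channels_in / bottleneck_ratio` width, floored, minimum 1).
#' @param gn_groups requested group-norm group count; clamped per layer to
#'   the largest divisor of the normalized channel count.
#' @param ca_reduction squeeze ratio of SE channel attention; must divide the
#'   channel count.
#' @return a `block_config` list.
#' @export
block_config <- function(channels_in, channels_out = channels_in,
                         bottleneck_ratio = min(4L, channels_in),
                         gn_groups = 8L, ca_reduction = 16L) {
  if (bottleneck_ratio > channels_in) {
    stop("configuration error: bottleneck_ratio exceeds channels_in")
  }
  structure(list(channels_in = as.integer(channels_in),
                 channels_out = as.integer(channels_out),
                 bottleneck_ratio = as.integer(bottleneck_ratio),
                 gn_groups = as.integer(gn_groups),
                 ca_reduction = as.integer(ca_reduction)),
            class = "block_config")
}

#' Create a CGR block (3x3 convolution, group normalization, ReLU)
#'
#' @param cfg a [block_config()].
#' @param stride convolution stride (1 preserves spatial extents).
#' @return a module; apply with [cgr()].
#' @export
new_cgr <- function(cfg, stride = 1L) {
  conv <- new_conv(cfg$channels_in, cfg$channels_out, k = 3L, stride = stride)
  gn <- new_groupnorm(cfg$channels_out, cfg$gn_groups)
  m <- new_module("cgr", children = list(conv = conv, gn = gn))
  m$cfg <- cfg
  m$forward <- function(x) t_relu(gn$forward(conv$forward(x)))
  m
}

#' Apply a CGR block
#' @param mod module from [new_cgr()].
#' @param f feature tensor/array (batch, channels, H, W).
#' @return tensor with `channels_out` channels; elementwise nonnegative.
#' @export
cgr <- function(mod, f) mod$forward(as_tn(f))

#' Create a BGR block (bottleneck convolution, group normalization, ReLU)
#'
#' The bottleneck is realized as 1x1 reduce -> 3x3 -> 1x1 expand, followed by
#' group normalization and ReLU.
#'
#' @param cfg a [block_config()].
#' @return a module; apply with [bgr()].
#' @export
new_bgr <- function(cfg) {
  mid <- max(1L, cfg$channels_in %/% cfg$bottleneck_ratio)
  reduce <- new_conv(cfg$channels_in, mid, k = 1L)
  core <- new_conv(mid, mid, k = 3L)
  expand <- new_conv(mid, cfg$channels_out, k = 1L)
  gn <- new_groupnorm(cfg$channels_out, cfg$gn_groups)
  m <- new_module("bgr", children = list(reduce = reduce, core = core,
                                         expand = expand, gn = gn))
  m$cfg <- cfg
  m$forward <- function(x) t_relu(gn$forward(expand$forward(core$forward(reduce$forward(x)))))
  m
}

#' Apply a BGR block
#' @inheritParams cgr
#' @param mod module from [new_bgr()].
#' @return tensor with `channels_out` channels; elementwise nonnegative.
#' @export
bgr <- function(mod, f) mod$forward(as_tn(f))

# Effective squeeze ratio used by the assembled network: the largest divisor
# of C not exceeding the requested ratio, additionally capped so the hidden
# layer keeps at least min(4, C) units -- a one-unit ReLU bottleneck has a
# ~50% chance of being dead at initialization, which stalls the gate.
se_reduction <- function(C, requested = 16L) {
  cap <- max(1L, C %/% min(4L, C))
  fit_groups(C, min(as.integer(requested), cap))
}

#' Create an SE-style channel attention block
#'
#' Squeeze (global average pool) -> 1x1 conv to `C / ca_reduction` -> ReLU ->
#' 1x1 conv back to `C` -> sigmoid; the input is rescaled per channel by the
#' resulting weights, which lie strictly in (0, 1).
#'
#' @param cfg a [block_config()]; `channels_in` must be divisible by
#'   `ca_reduction`.
#' @return a module; apply with [channel_attention_se()].
#' @export
new_se <- function(cfg) {
  C <- cfg$channels_in
  red <- cfg$ca_reduction
  if (C %% red != 0L) {
    stop(sprintf("configuration error: ca_reduction %d does not divide %d channels", red, C))
  }
  hidden <- max(1L, C %/% red)
  fc1 <- new_conv(C, hidden, k = 1L)
  fc2 <- new_conv(hidden, C, k = 1L)
  m <- new_module("se", children = list(fc1 = fc1, fc2 = fc2))
  m$cfg <- cfg
  m$weights <- function(x) {
    t_sigmoid(fc2$forward(t_relu(fc1$forward(t_gap(as_tn(x))))))
  }
  m$forward <- function(x) {
    x <- as_tn(x)
    t_mul(x, m$weights(x))
  }
  m
}

#' Apply SE channel attention
#' @inheritParams cgr
#' @param mod module from [new_se()].
#' @return the input rescaled per channel by weights strictly in (0, 1).
#' @export
channel_attention_se <- function(mod, f) mod$forward(as_tn(f))
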