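# Hierarchical five-level encoder with foreground-background attention (FBA)
# at every scale.  The backbone is a configurable stage-wise convolutional
# encoder (stride-4 stem, then four stride-2 stages), optionally inserting a
# selective-scan block per stage; it exposes the same five-level contract as
# the hybrid mobile state-space backbone it stands in for, so a faithful port
# can be dropped in behind `extract_pyramid()` later.

#' Encoder configuration
#'
#' @param channels five nondecreasing channel counts C1..C5 for pyramid
#'   levels at strides 4, 8, 16, 32, 64.
#' @param stem_stride stride of the input stem (4: input -> level 1).
#' @param use_ssm_stages logical flags (length 5): append a selective-scan
#'   block with a residual connection inside the corresponding stage.
#' @param fba_enabled apply foreground-background attention at every level
#'   (ablation switch).
#' @param state_dim state dimension of in-encoder selective-scan blocks.
#' @param gn_groups requested group-norm groups for encoder blocks.
#' @return an `encoder_config` list.
#' @export
encoder_config <- function(channels = c(16L, 32L, 64L, 96L, 128L),
                           stem_stride = 4L,
                           use_ssm_stages = rep(FALSE, 5),
                           fba_enabled = TRUE,
                           state_dim = 16L,
                           gn_groups = 8L) {
  channels <- as.integer(channels)
  if (length(channels) != 5L) stop("encoder channels must have 5 entries")
  if (is.unsorted(channels)) stop("encoder channels must be nondecreasing")
  if (length(use_ssm_stages) != 5L) use_ssm_stages <- rep(use_ssm_stages, length.out = 5L)
  structure(list(channels = channels, stem_stride = as.integer(stem_stride),
                 use_ssm_stages = as.logical(use_ssm_stages),
                 fba_enabled = isTRUE(fba_enabled),
                 state_dim = as.integer(state_dim),
                 gn_groups = as.integer(gn_groups)),
            class = "encoder_config")
}

#' Create a foreground-background attention (FBA) block
#'
#' Sequential channel attention (SE) then spatial attention (channel-pooled
#' max+mean maps through a 7x7 convolution and a sigmoid gate), with a
#' residual addition: `FBA(f) = SA(CA(f)) + f`.
#'
#' @param C channel count of the feature it gates.
#' @param ca_reduction requested SE squeeze ratio (clamped to a divisor of `C`).
#' @return a module; apply with [fba()].
#' @export
new_fba <- function(C, ca_reduction = 16L) {
  ca <- new_se(block_config(C, C, ca_reduction = se_reduction(C, ca_reduction)))
  sa_conv <- new_conv(2L, 1L, k = 7L)
  m <- new_module("fba", children = list(ca = ca, sa_conv = sa_conv))
  m$sa <- function(x) {
    x <- as_tn(x)
    t_mul(x, t_sigmoid(sa_conv$forward(t_chan_maxmean(x))))
  }
  m$forward <- function(x) {
    x <- as_tn(x)
    t_add(m$sa(ca$forward(x)), x)
  }
  m
}

#' Apply foreground-background attention
#' @param mod module from [new_fba()].
#' @param f feature tensor/array (batch, channels, H, W).
#' @return tensor with the extents of `f`.
#' @export
fba <- function(mod, f) mod$forward(as_tn(f))

# One encoder stage: strided CGR followed by a stride-1 CGR, optionally a
# selective-scan residual block.
new_encoder_stage <- function(cin, cout, stride, use_ssm, state_dim, gn_groups) {
  down <- new_cgr(block_config(cin, cout, gn_groups = gn_groups), stride = stride)
  refine <- new_cgr(block_config(cout, cout, gn_groups = gn_groups))
  ch <- list(down = down, refine = refine)
  if (use_ssm) ch$ssm <- new_ss2d(cout, state_dim)
  m <- new_module("encoder_stage", children = ch)
  m$forward <- function(x) {
    y <- refine$forward(down$forward(x))
    if (!is.null(ch$ssm)) y <- t_add(y, ch$ssm$forward(y))
    y
  }
  m
}

#' Create the hierarchical encoder
#' @param cfg an [encoder_config()].
#' @param in_channels input image channels (3 for RGB).
#' @return a module; apply with [extract_pyramid()].
#' @export
new_encoder <- function(cfg = encoder_config(), in_channels = 3L) {
  chs <- cfg$channels
  stages <- list(new_encoder_stage(in_channels, chs[1], cfg$stem_stride,
                                   cfg$use_ssm_stages[1], cfg$state_dim, cfg$gn_groups))
  for (i in 2:5) {
    stages[[i]] <- new_encoder_stage(chs[i - 1], chs[i], 2L,
                                     cfg$use_ssm_stages[i], cfg$state_dim, cfg$gn_groups)
  }
  names(stages) <- paste0("stage", 1:5)
  fbas <- list()
  if (cfg$fba_enabled) {
    fbas <- lapply(chs, new_fba)
    names(fbas) <- paste0("fba", 1:5)
  }
  m <- new_module("encoder", children = c(stages, fbas))
  m$cfg <- cfg
  m$forward <- function(images) {
    x <- as_tn(images)
    d <- dim(x$v)
    div <- cfg$stem_stride * 16L
    if (d[3] %% div != 0L || d[4] %% div != 0L) {
      stop(sprintf("input error: image height and width must be divisible by %d", div))
    }
    levels <- vector("list", 5L)
    for (i in 1:5) {
      x <- stages[[i]]$forward(x)
      levels[[i]] <- if (cfg$fba_enabled) fbas[[i]]$forward(x) else x
    }
    structure(levels, class = "feature_pyramid")
  }
  m
}

#' Extract the five-level feature pyramid
#'
#' Runs the encoder (and, when enabled, FBA at every scale) on a batch of
#' images, producing features at strides 4, 8, 16, 32 and 64 relative to the
#' input.
#'
#' @param enc module from [new_encoder()].
#' @param images array/tensor (batch, channels, H, W); H and W must be
#'   divisible by 64.
#' @return a `feature_pyramid`: list of 5 tensors, level i with spatial
#'   extents `(H, W) / 2^(i+1)` and the configured channel counts.
#' @export
extract_pyramid <- function(enc, images) enc$forward(images)
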