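# Full network assembly: encoder + FBA pyramid, top-down decoder alternating
# ASM (refine + 2x upsample + channel projection), LALGA (channel
# recalibration on both TPFF inputs) and TPFF (cross-level fusion), closed by
# a small segmentation head (bilinear 2x upsample, 1x1 convolution to one
# channel, sigmoid).
#
# Per forward pass the decoder invokes ASM 5 times (levels 5..1), LALGA 8
# times (the high-level input at levels 2..5 and the lateral input at levels
# 1..4) and TPFF 4 times (levels 4..1).

#' Model configuration
#'
#' @param preset `"tiny"` (64x64 inputs, channels 8/16/24/32/48, state
#'   dimension 8; CPU-friendly) or `"paper"` (256x256 inputs, channels
#'   16/32/64/96/128, state dimension 16).
#' @param channels optional override of the five encoder channel counts.
#' @param state_dim optional override of the selective-scan state dimension.
#' @param input_size expected square input extent (must be divisible by 64).
#' @param ablation named logical list over `fba`, `asm`, `lalga`, `tpff`;
#'   disabling a module substitutes the identity (plain addition for TPFF)
#'   while preserving all extents.
#' @param tpff_paths named logical vector over `cp`, `sp`, `dp`.
#' @param init_coefficients initial TPFF simplex point.
#' @param ffn_expansion,ggca_reduction,bottleneck_ratio,gn_groups,ca_reduction
#'   block hyperparameters.
#' @param use_ssm_stages encoder per-stage selective-scan flags.
#' @param threshold default binarization threshold of [predict_mask()].
#' @return an `ltpnet_config` list.
#' @export
ltpnet_config <- function(preset = c("tiny", "paper"),
                          channels = NULL, state_dim = NULL,
                          input_size = NULL,
                          ablation = list(fba = TRUE, asm = TRUE,
                                          lalga = TRUE, tpff = TRUE),
                          tpff_paths = c(cp = TRUE, sp = TRUE, dp = TRUE),
                          init_coefficients = c(0.4, 0.2, 0.4),
                          ffn_expansion = 4L, ggca_reduction = 4L,
                          bottleneck_ratio = 4L, gn_groups = 8L,
                          ca_reduction = 16L,
                          use_ssm_stages = rep(FALSE, 5),
                          threshold = 0.5) {
  preset <- match.arg(preset)
  if (is.null(channels)) {
    channels <- if (preset == "tiny") c(8L, 16L, 24L, 32L, 48L) else c(16L, 32L, 64L, 96L, 128L)
  }
  if (is.null(state_dim)) state_dim <- if (preset == "tiny") 8L else 16L
  if (is.null(input_size)) input_size <- if (preset == "tiny") 64L else 256L
  ab <- list(fba = TRUE, asm = TRUE, lalga = TRUE, tpff = TRUE)
  ab[names(ablation)] <- lapply(ablation, isTRUE)
  structure(list(preset = preset, channels = as.integer(channels),
                 state_dim = as.integer(state_dim),
                 input_size = as.integer(input_size),
                 ablation = ab, tpff_paths = tpff_paths,
                 init_coefficients = init_coefficients,
                 ffn_expansion = as.integer(ffn_expansion),
                 ggca_reduction = as.integer(ggca_reduction),
                 bottleneck_ratio = as.integer(bottleneck_ratio),
                 gn_groups = as.integer(gn_groups),
                 ca_reduction = as.integer(ca_reduction),
                 use_ssm_stages = as.logical(use_ssm_stages),
                 threshold = threshold),
            class = "ltpnet_config")
}

# Identity stand-in used by ablation switches.
new_identity <- function() {
  m <- new_module("identity")
  m$forward <- function(x) as_tn(x)
  m
}

#' Build the segmentation network
#'
#' @param cfg an [ltpnet_config()].
#' @param seed optional integer; when given, parameter initialization is
#'   seeded (the caller's RNG state is restored afterwards).
#' @return a model module; run with [ltpnet_forward()] / [predict_mask()].
#' @export
ltpnet <- function(cfg = ltpnet_config(), seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  chs <- cfg$channels
  ab <- cfg$ablation
  enc <- new_encoder(encoder_config(channels = chs,
                                    use_ssm_stages = cfg$use_ssm_stages,
                                    fba_enabled = ab$fba,
                                    state_dim = cfg$state_dim,
                                    gn_groups = cfg$gn_groups))
  # ASM at level i maps C_i -> C_{i-1} (C_1 -> C_1 at the last level).
  asms <- list()
  for (i in 5:1) {
    tgt <- if (i > 1) chs[i - 1] else chs[1]
    asms[[paste0("asm", i)]] <- new_asm(chs[i], tgt,
                                        state_dim = cfg$state_dim,
                                        ffn_expansion = cfg$ffn_expansion,
                                        gn_groups = cfg$gn_groups,
                                        core_enabled = ab$asm)
  }
  mk_lalga <- function(C) {
    if (ab$lalga) new_lalga(C, cfg$ggca_reduction, cfg$bottleneck_ratio, cfg$gn_groups)
    else new_identity()
  }
  lalga_hi <- list(); lalga_lo <- list()
  for (i in 2:5) lalga_hi[[paste0("lalga_hi", i)]] <- mk_lalga(chs[i - 1])
  for (i in 1:4) lalga_lo[[paste0("lalga_lo", i)]] <- mk_lalga(chs[i])
  tpffs <- list()
  if (ab$tpff) {
    for (i in 1:4) {
      tpffs[[paste0("tpff", i)]] <- new_tpff(chs[i], enabled_paths = cfg$tpff_paths,
                                             init_coefficients = cfg$init_coefficients,
                                             bottleneck_ratio = cfg$bottleneck_ratio,
                                             gn_groups = cfg$gn_groups,
                                             ca_reduction = cfg$ca_reduction)
    }
  }
  head_conv <- new_conv(chs[1], 1L, k = 1L)
  model <- new_module("ltpnet",
                      children = c(list(encoder = enc), asms, lalga_hi, lalga_lo,
                                   tpffs, list(head_conv = head_conv)))
  model$cfg <- cfg
  counts <- new.env(parent = emptyenv())
  model$counts <- counts
  model$tpffs <- tpffs

  model$forward <- function(images) {
    counts$asm <- 0L; counts$lalga <- 0L; counts$tpff <- 0L
    pyr <- enc$forward(images)
    run_asm <- function(i, f) { counts$asm <- counts$asm + 1L; asms[[paste0("asm", i)]]$forward(f) }
    run_lalga <- function(mod, f) { counts$lalga <- counts$lalga + 1L; mod$forward(f) }
    f_asm <- run_asm(5L, pyr[[5]])
    for (i in 4:1) {
      f_hi <- run_lalga(lalga_hi[[paste0("lalga_hi", i + 1L)]], f_asm)
      f_lo <- run_lalga(lalga_lo[[paste0("lalga_lo", i)]], pyr[[i]])
      dh <- dim(tn_value(f_hi)); dl <- dim(tn_value(f_lo))
      if (!identical(dh, dl)) {
        stop(sprintf("TPFF junction mismatch at level %d: %s vs %s", i,
                     paste(dh, collapse = "x"), paste(dl, collapse = "x")))
      }
      counts$tpff <- counts$tpff + 1L
      f_tpff <- if (ab$tpff) tpffs[[paste0("tpff", i)]]$forward(f_hi, f_lo)
                else t_add(f_hi, f_lo)
      f_asm <- run_asm(i, f_tpff)
    }
    t_sigmoid(head_conv$forward(t_upsample_bilinear(f_asm, 2L)))
  }
  model
}

#' Run the network
#'
#' @param model module from [ltpnet()].
#' @param images array/tensor (batch, 3, H, W) with H, W divisible by 64.
#' @return probability-map tensor (batch, 1, H, W) with values in `[0, 1]`.
#' @export
ltpnet_forward <- function(model, images) model$forward(images)

#' Invocation counts of the last forward pass
#' @param model module from [ltpnet()].
#' @return named integer vector (`asm`, `lalga`, `tpff`).
#' @export
ltpnet_counts <- function(model) {
  c(asm = model$counts$asm, lalga = model$counts$lalga, tpff = model$counts$tpff)
}

#' Predict binary masks
#'
#' A pixel is predicted positive iff its probability is greater than or equal
#' to `threshold` (documented tie rule).
#'
#' @param model module from [ltpnet()].
#' @param images array/tensor (batch, 3, H, W).
#' @param threshold probability cut in the open interval (0, 1).
#' @return integer 0/1 array (batch, 1, H, W).
#' @export
predict_mask <- function(model, images, threshold = model$cfg$threshold) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop("configuration error: threshold must lie strictly in (0, 1)")
  }
  probs <- ag_no_grad(tn_value(model$forward(images)))
  array(as.integer(probs >= threshold), dim(probs))
}
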