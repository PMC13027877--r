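# Triple-path feature fusion (TPFF).  Both cross-level inputs are projected
# by BGR blocks, then fused along three parallel pathways -- common (add),
# saliency (multiply), difference (subtract) -- each refined by SE channel
# attention with the residual convention of the design: the common path adds
# its own sum back, while saliency and difference add the LOW-level input.
# The three pathway outputs are combined with simplex-constrained learnable
# coefficients realized as a softmax over three logits, initialized so the
# coefficients start at exactly (0.4, 0.2, 0.4).

#' Normalize fusion coefficient logits onto the simplex
#'
#' `(alpha, beta, gamma) = softmax(logits)`: strictly positive and summing to
#' 1 up to machine epsilon.  The default logits `log(c(0.4, 0.2, 0.4))` give
#' initial coefficients exactly (0.4, 0.2, 0.4).
#'
#' @param logits three finite reals.
#' @return a `fusion_coefficients` list with `alpha`, `beta`, `gamma`.
#' @export
normalize_coefficients <- function(logits = log(c(0.4, 0.2, 0.4))) {
  logits <- as.numeric(logits)
  if (length(logits) != 3L || any(!is.finite(logits))) {
    stop("numeric error: logits must be three finite reals")
  }
  s <- exp(logits - max(logits))
  s <- s / sum(s)
  structure(list(alpha = s[1], beta = s[2], gamma = s[3]),
            class = "fusion_coefficients")
}

# Differentiable softmax restricted to `active` components; inactive entries
# get coefficient 0 (their mass renormalized over the active paths).
t_softmax_subset <- function(logits, active) {
  logits <- as_tn(logits)
  z <- as.numeric(logits$v)[active]
  s <- exp(z - max(z)); s <- s / sum(s)
  out <- numeric(length(logits$v))
  out[active] <- s
  ag_node(out, list(logits), function(g) {
    g <- as.numeric(g)[active]
    d <- numeric(length(logits$v))
    d[active] <- s * (g - sum(g * s))
    list(d)
  })
}

#' Create a triple-path feature fusion (TPFF) block
#'
#' @param C channel count at this decoder level (both inputs are projected
#'   to `C` by BGR blocks).
#' @param enabled_paths named logical vector over `c("cp", "sp", "dp")`;
#'   disabling a path removes it and renormalizes the coefficient mass over
#'   the active paths (structural ablation).
#' @param init_coefficients initial simplex point; logits start at its log.
#' @param bottleneck_ratio,gn_groups,ca_reduction block hyperparameters
#'   (`ca_reduction` is clamped to a divisor of `C`).
#' @return a module; apply with [tpff_forward()].
#' @export
new_tpff <- function(C, enabled_paths = c(cp = TRUE, sp = TRUE, dp = TRUE),
                     init_coefficients = c(0.4, 0.2, 0.4),
                     bottleneck_ratio = 4L, gn_groups = 8L,
                     ca_reduction = 16L) {
  if (any(init_coefficients <= 0)) stop("init_coefficients must be positive")
  bcfg <- block_config(C, C, bottleneck_ratio = min(bottleneck_ratio, C),
                       gn_groups = gn_groups)
  secfg <- block_config(C, C, ca_reduction = se_reduction(C, ca_reduction))
  ch <- list(proj_low = new_bgr(bcfg), proj_high = new_bgr(bcfg),
             ca_cp = new_se(secfg), ca_sp = new_se(secfg), ca_dp = new_se(secfg))
  logits <- tn_tensor(log(as.numeric(init_coefficients)), requires_grad = TRUE)
  m <- new_module("tpff", params = list(logits = logits), children = ch)
  m$enabled <- c(cp = isTRUE(enabled_paths[["cp"]]),
                 sp = isTRUE(enabled_paths[["sp"]]),
                 dp = isTRUE(enabled_paths[["dp"]]))
  if (!any(m$enabled)) stop("at least one TPFF path must be enabled")
  m$cp <- function(flow, fhigh) {
    fcp <- t_add(flow, fhigh)
    t_add(ch$ca_cp$forward(fcp), fcp)
  }
  m$sp <- function(flow, fhigh) {
    t_add(ch$ca_sp$forward(t_mul(flow, fhigh)), flow)
  }
  m$dp <- function(flow, fhigh) {
    t_add(ch$ca_dp$forward(t_sub(flow, fhigh)), flow)
  }
  m$coefficients <- function() {
    tn_value(t_softmax_subset(m$params$logits, which(m$enabled)))
  }
  m$forward <- function(f_high_lala, f_low_lala) {
    fhigh <- ch$proj_high$forward(as_tn(f_high_lala))
    flow <- ch$proj_low$forward(as_tn(f_low_lala))
    if (!identical(dim(tn_value(flow)), dim(tn_value(fhigh)))) {
      stop("shape error: TPFF inputs differ in extents after projection")
    }
    coef <- t_softmax_subset(m$params$logits, which(m$enabled))
    zero <- array(0, dim(tn_value(flow)))
    p1 <- if (m$enabled[["cp"]]) m$cp(flow, fhigh) else tn_tensor(zero)
    p2 <- if (m$enabled[["sp"]]) m$sp(flow, fhigh) else tn_tensor(zero)
    p3 <- if (m$enabled[["dp"]]) m$dp(flow, fhigh) else tn_tensor(zero)
    t_lincomb3(p1, p2, p3, coef)
  }
  m
}

#' Fusion coefficients of a TPFF block
#' @param mod module from [new_tpff()].
#' @return numeric `(alpha, beta, gamma)`; zeros for disabled paths, the
#'   rest strictly positive and summing to 1.
#' @export
tpff_coefficients <- function(mod) {
  co <- mod$coefficients()
  names(co) <- c("alpha", "beta", "gamma")
  co
}

#' Common path: `CA(flow + fhigh) + (flow + fhigh)`
#' @param mod module from [new_tpff()].
#' @param flow,fhigh projected low/high-level features with equal extents.
#' @return fused tensor.
#' @export
common_path <- function(mod, flow, fhigh) {
  flow <- as_tn(flow); fhigh <- as_tn(fhigh)
  if (!identical(dim(tn_value(flow)), dim(tn_value(fhigh)))) {
    stop("shape error: extents differ")
  }
  mod$cp(flow, fhigh)
}

#' Saliency path: `CA(flow * fhigh) + flow` (residual uses the low input)
#' @inheritParams common_path
#' @export
saliency_path <- function(mod, flow, fhigh) {
  flow <- as_tn(flow); fhigh <- as_tn(fhigh)
  if (!identical(dim(tn_value(flow)), dim(tn_value(fhigh)))) {
    stop("shape error: extents differ")
  }
  mod$sp(flow, fhigh)
}

#' Difference path: `CA(flow - fhigh) + flow` (residual uses the low input)
#' @inheritParams common_path
#' @export
difference_path <- function(mod, flow, fhigh) {
  flow <- as_tn(flow); fhigh <- as_tn(fhigh)
  if (!identical(dim(tn_value(flow)), dim(tn_value(fhigh)))) {
    stop("shape error: extents differ")
  }
  mod$dp(flow, fhigh)
}

#' Apply triple-path feature fusion
#'
#' Projects both inputs with BGR blocks, evaluates the enabled pathways and
#' combines them with the simplex-normalized coefficients:
#' `out = alpha*CP + beta*SP + gamma*DP`.
#'
#' @param mod module from [new_tpff()].
#' @param f_high_lala higher-level refined feature (already upsampled to this
#'   level's extents).
#' @param f_low_lala same-level refined encoder feature.
#' @return fused tensor with the projected inputs' extents.
#' @export
tpff_forward <- function(mod, f_high_lala, f_low_lala) {
  mod$forward(f_high_lala, f_low_lala)
}
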