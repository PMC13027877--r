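# Four-direction 2-D selective scan (SS2D).
#
# The feature map is unfolded along four structured paths (row-major
# forward/backward, column-major forward/backward) into 1-D sequences.  Each
# sequence runs through an input-dependent linear state-space recurrence
#
#     h_t = exp(Delta_t * A) h_{t-1} + Delta_t B_t x_t
#     y_t = C_t . h_t + D x_t
#
# with per-direction parameters: A = -exp(logA), a negative per-(state,
# channel) decay; Delta_t = softplus(Wd x_t + bd), a positive per-channel
# step size; B_t = WB x_t and C_t = WC x_t, per-position state projections
# shared across channels; and D, a per-channel skip gain.  The four
# directional outputs are folded back to 2-D and summed.  The sequential
# recurrence and its hand-derived backward pass run as compiled kernels and
# are validated against a naive per-timestep R oracle and finite differences
# in the test-suite.

# Position orderings for the four scan paths of an H x W map whose spatial
# positions are indexed column-major (p = h + H*(w-1)).
scan_orders <- function(H, W) {
  T_ <- H * W
  cf <- seq_len(T_)                                  # column-major, top->bottom
  rf <- as.vector(t(matrix(cf, H, W)))               # row-major, left->right
  list(row_f = rf, row_b = rev(rf), col_f = cf, col_b = rev(cf))
}

# Unfold (B,C,H,W) into the four scan sequences, each (B,C,T).
ss2d_unfold <- function(x) {
  d <- dim(x)
  xf <- x
  dim(xf) <- c(d[1], d[2], d[3] * d[4])
  lapply(scan_orders(d[3], d[4]), function(od) xf[, , od, drop = FALSE])
}

# Fold one direction's sequence (B,C,T) back to (B,C,H,W); exact inverse of
# the corresponding unfold permutation.
ss2d_fold <- function(seq_, direction, H, W) {
  od <- scan_orders(H, W)[[direction]]
  d <- dim(seq_)
  out <- array(0, c(d[1], d[2], H * W))
  out[, , od] <- seq_
  dim(out) <- c(d[1], d[2], H, W)
  out
}

# Core differentiable primitive.  Parameter tensors are stacked over the 4
# directions: logA (N,C,4), Wd (C,C,4), bd (C,4), WB (N,C,4), WC (N,C,4),
# D (C,4).
t_ss2d <- function(x, logA, Wd, bd, WB, WC, D) {
  x <- as_tn(x)
  dm <- dim(x$v)
  ords <- scan_orders(dm[3], dm[4])
  om <- cbind(ords$row_f, ords$row_b, ords$col_f, ords$col_b) - 1L
  fw <- cpp_ss2d_forward(x$v, logA$v, Wd$v, bd$v, WB$v, WC$v, D$v, om)
  ag_node(fw$out, list(x, logA, Wd, bd, WB, WC, D), function(g) {
    bw <- cpp_ss2d_backward(x$v, logA$v, Wd$v, bd$v, WB$v, WC$v, D$v, om,
                            fw$Hall, fw$Delta, fw$draw, fw$Bt, fw$Ct, g)
    list(if (x$rq) bw$dx else NULL,
         if (logA$rq) bw$dlogA else NULL,
         if (Wd$rq) bw$dWd else NULL,
         if (bd$rq) bw$dbd else NULL,
         if (WB$rq) bw$dWB else NULL,
         if (WC$rq) bw$dWC else NULL,
         if (D$rq) bw$dD else NULL)
  })
}

# SS2D module: owns the four direction parameter sets for a fixed channel
# count.  Initialization follows common state-space practice: A_n = -n
# (logA = log n), step size biased so softplus(bd) ~ 0.05, small random
# input/output projections, unit skip gain.
new_ss2d <- function(C, state_dim = 16L) {
  N <- as.integer(state_dim)
  logA <- tn_tensor(array(rep(log(seq_len(N)), C * 4), c(N, C, 4)), requires_grad = TRUE)
  Wd <- tn_tensor(array(stats::rnorm(C * C * 4, 0, 0.05 / sqrt(C)), c(C, C, 4)), requires_grad = TRUE)
  bd <- tn_tensor(array(log(expm1(0.05)), c(C, 4)), requires_grad = TRUE)
  WB <- tn_tensor(array(stats::rnorm(N * C * 4, 0, 1 / sqrt(C)), c(N, C, 4)), requires_grad = TRUE)
  WC <- tn_tensor(array(stats::rnorm(N * C * 4, 0, 1 / sqrt(N)), c(N, C, 4)), requires_grad = TRUE)
  D <- tn_tensor(array(1, c(C, 4)), requires_grad = TRUE)
  m <- new_module("ss2d", params = list(logA = logA, Wd = Wd, bd = bd,
                                        WB = WB, WC = WC, D = D))
  m$state_dim <- N
  m$forward <- function(x) t_ss2d(x, m$params$logA, m$params$Wd, m$params$bd,
                                  m$params$WB, m$params$WC, m$params$D)
  m
}

#' Apply a 2-D selective scan module
#'
#' Runs the four-direction selective scan over a feature map and sums the
#' folded directional outputs.  With the output projection frozen to zero and
#' unit skip gain the block degenerates to `4 * f`.
#'
#' @param mod an SS2D module (see [new_asm()] or `ltpnet:::new_ss2d`).
#' @param f feature map tensor or array, dims (batch, channels, H, W).
#' @return a tensor with the extents of `f`.
#' @export
ss2d <- function(mod, f) mod$forward(as_tn(f))
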