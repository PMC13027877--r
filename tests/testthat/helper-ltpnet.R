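# Shared test helpers: independent numerical oracles (finite differences,
# naive convolution / normalization / selective-scan recurrences written as
# direct loops) and parameter-freezing utilities.

num_grad <- function(fn, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (fn(xp) - fn(xm)) / (2 * eps)
  }
  g
}

# Direct-loop "same"-padded convolution, independent of the package kernels.
naive_conv2d <- function(x, w, b = NULL, stride = 1L, pad = NULL) {
  dw <- dim(w); Cin <- dw[1]; k <- dw[2]; Cout <- dw[4]
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  d <- dim(x)
  Ho <- (d[3] + 2L * pad - k) %/% stride + 1L
  Wo <- (d[4] + 2L * pad - k) %/% stride + 1L
  out <- array(0, c(d[1], Cout, Ho, Wo))
  for (bb in seq_len(d[1])) for (co in seq_len(Cout)) {
    for (ho in seq_len(Ho)) for (wo in seq_len(Wo)) {
      acc <- if (is.null(b)) 0 else b[co]
      for (ci in seq_len(Cin)) for (ky in seq_len(k)) for (kx in seq_len(k)) {
        y <- (ho - 1L) * stride + ky - pad
        xcol <- (wo - 1L) * stride + kx - pad
        if (y >= 1 && y <= d[3] && xcol >= 1 && xcol <= d[4]) {
          acc <- acc + x[bb, ci, y, xcol] * w[ci, ky, kx, co]
        }
      }
      out[bb, co, ho, wo] <- acc
    }
  }
  out
}

naive_groupnorm <- function(x, gamma, beta, groups, eps = 1e-5) {
  d <- dim(x)
  cs <- d[2] %/% groups
  out <- x
  for (bb in seq_len(d[1])) for (g in seq_len(groups)) {
    chs <- (g - 1L) * cs + seq_len(cs)
    v <- x[bb, chs, , , drop = FALSE]
    mu <- mean(v)
    va <- mean((v - mu)^2)
    for (c in chs) {
      out[bb, c, , ] <- (x[bb, c, , ] - mu) / sqrt(va + eps) * gamma[c] + beta[c]
    }
  }
  out
}

# Brute-force per-timestep selective-scan recurrence over the four paths,
# written as plain nested loops against the module's parameter values.
naive_ss2d <- function(x, mod) {
  p <- lapply(mod$params, function(t) t$v)
  d <- dim(x); B <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  N <- dim(p$logA)[1]
  A <- -exp(p$logA)
  ords <- ltpnet:::scan_orders(H, W)
  xf <- x; dim(xf) <- c(B, C, H * W)
  out <- array(0, c(B, C, H * W))
  for (dd in 1:4) {
    od <- ords[[dd]]
    for (bb in seq_len(B)) {
      h <- matrix(0, N, C)
      for (t in seq_along(od)) {
        xt <- xf[bb, , od[t]]
        delta <- log1p(exp(pmin(p$Wd[, , dd] %*% xt + p$bd[, dd], 30)))
        Bt <- p$WB[, , dd] %*% xt
        Ct <- p$WC[, , dd] %*% xt
        for (c in seq_len(C)) {
          h[, c] <- exp(delta[c] * A[, c, dd]) * h[, c] + delta[c] * Bt * xt[c]
          out[bb, c, od[t]] <- out[bb, c, od[t]] + sum(Ct * h[, c]) + p$D[c, dd] * xt[c]
        }
      }
    }
  }
  dim(out) <- d
  out
}

# O(n^2) pairwise Mann-Whitney AUC oracle (ties count 1/2).
auc_pairwise <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# Set every parameter of a module (recursively) to zero.
zero_params <- function(mod) {
  ltpnet::module_parameters(mod) |> lapply(function(p) { p$v[] <- 0; NULL })
  invisible(mod)
}

# Freeze a BGR block to emit all-ones: zero the expand conv, set the group
# norm to output its beta = 1.
freeze_bgr_to_ones <- function(bgr_mod) {
  bgr_mod$children$expand$params$w$v[] <- 0
  bgr_mod$children$expand$params$b$v[] <- 0
  bgr_mod$children$gn$params$gamma$v[] <- 0
  bgr_mod$children$gn$params$beta$v[] <- 1
  invisible(bgr_mod)
}

# Set a 1x1 conv to the identity map (square channel counts, zero bias).
set_identity_1x1 <- function(conv_mod) {
  w <- conv_mod$params$w$v
  w[] <- 0
  for (c in seq_len(dim(w)[1])) w[c, 1, 1, c] <- 1
  conv_mod$params$w$v <- w
  conv_mod$params$b$v[] <- 0
  invisible(conv_mod)
}

# Random feature tensor with reproducible contents.
rand_feat <- function(B, C, H, W, seed = 1) {
  set.seed(seed)
  array(stats::rnorm(B * C * H * W), c(B, C, H, W))
}

tv <- ltpnet::tn_value

make_synth_pairs <- function(n, seed0 = 1, size = 64L) {
  lapply(seq_len(n), function(i) {
    generate_lesion_image(synth_params(image_size = c(size, size), seed = seed0 + i - 1L))
  })
}
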