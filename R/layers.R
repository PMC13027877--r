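# Parameterized layers built on the autodiff core: dense and depthwise 2-D
# convolutions (im2col + BLAS), group/batch normalization, and bilinear
# upsampling.  Weight layout for a dense conv is (Cin, kh, kw, Cout) so that
# flattening matches the im2col column order (channel fastest, then kernel
# row, then kernel column).

pad4 <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1], d[2], d[3] + 2L * p, d[4] + 2L * p))
  xp[, , p + seq_len(d[3]), p + seq_len(d[4])] <- x
  xp
}

# Dense 2-D convolution (compiled im2col + BLAS kernel).  w: tensor
# (Cin,k,k,Cout); b: tensor length Cout or NULL.  "Same" padding by default
# for stride 1 and odd k.
t_conv2d <- function(x, w, b = NULL, stride = 1L, pad = NULL) {
  x <- as_tn(x); w <- as_tn(w)
  if (!is.null(b)) b <- as_tn(b)
  dw <- dim(w$v)
  Cin <- dw[1]; k <- dw[2]
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  d <- dim(x$v)
  if (d[2] != Cin) stop(sprintf("conv2d: input has %d channels, weight expects %d", d[2], Cin))
  out <- cpp_conv2d_forward(x$v, w$v, if (is.null(b)) NULL else as.numeric(b$v),
                            as.integer(stride), as.integer(pad))
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ag_node(out, parents, function(g) {
    bw <- cpp_conv2d_backward(x$v, w$v, g, as.integer(stride), as.integer(pad),
                              x$rq, w$rq, !is.null(b) && b$rq)
    if (is.null(b)) list(bw$dx, bw$dw) else list(bw$dx, bw$dw, bw$db)
  })
}

# Depthwise 3x3 (or kxk) convolution.  w: tensor (C,k,k); b length C or NULL.
t_dwconv2d <- function(x, w, b = NULL, stride = 1L, pad = NULL) {
  x <- as_tn(x); w <- as_tn(w)
  dw <- dim(w$v)
  C <- dw[1]; k <- dw[2]
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  d <- dim(x$v)
  if (d[2] != C) stop("dwconv2d: channel mismatch")
  Ho <- (d[3] + 2L * pad - k) %/% stride + 1L
  Wo <- (d[4] + 2L * pad - k) %/% stride + 1L
  xp <- pad4(x$v, pad)
  out <- array(0, c(d[1], C, Ho, Wo))
  slices <- vector("list", k * k)
  o <- 0L
  for (kx in seq_len(k)) {
    xs <- kx + stride * (seq_len(Wo) - 1L)
    for (ky in seq_len(k)) {
      ys <- ky + stride * (seq_len(Ho) - 1L)
      o <- o + 1L
      sl <- xp[, , ys, xs, drop = FALSE]
      slices[[o]] <- sl
      out <- out + sl * rep(w$v[, ky, kx], each = d[1])
    }
  }
  if (!is.null(b)) { b <- as_tn(b); out <- out + rep(as.numeric(b$v), each = d[1]) }
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ag_node(out, parents, function(g) {
    dW <- if (w$rq) array(0, dw) else NULL
    dx <- NULL
    dxp <- if (x$rq) array(0, dim(xp)) else NULL
    o <- 0L
    for (kx in seq_len(k)) {
      xs <- kx + stride * (seq_len(Wo) - 1L)
      for (ky in seq_len(k)) {
        ys <- ky + stride * (seq_len(Ho) - 1L)
        o <- o + 1L
        if (w$rq) {
          tmp <- g * slices[[o]]
          per_c <- rowSums(matrix(colSums(matrix(tmp, d[1], C * Ho * Wo)), C, Ho * Wo))
          dW[, ky, kx] <- per_c
        }
        if (x$rq) {
          dxp[, , ys, xs] <- dxp[, , ys, xs, drop = FALSE] + g * rep(w$v[, ky, kx], each = d[1])
        }
      }
    }
    if (x$rq) {
      dx <- if (pad > 0L) dxp[, , pad + seq_len(d[3]), pad + seq_len(d[4]), drop = FALSE] else dxp
    }
    db <- if (!is.null(b) && b$rq) {
      rowSums(matrix(colSums(matrix(g, d[1], C * Ho * Wo)), C, Ho * Wo))
    } else NULL
    if (is.null(b)) list(dx, dW) else list(dx, dW, db)
  })
}

# Group normalization over (channels-in-group, H, W) per sample (compiled
# kernel).  gamma, beta: length-C tensors.
t_groupnorm <- function(x, gamma, beta, groups, eps = 1e-5) {
  x <- as_tn(x); gamma <- as_tn(gamma); beta <- as_tn(beta)
  d <- dim(x$v)
  if (d[2] %% groups != 0L) stop("groupnorm: groups must divide channels")
  fw <- cpp_groupnorm_forward(x$v, as.numeric(gamma$v), as.numeric(beta$v),
                              as.integer(groups), eps)
  ag_node(fw$out, list(x, gamma, beta), function(g) {
    bw <- cpp_groupnorm_backward(x$v, as.numeric(gamma$v), fw$mu, fw$istd, g,
                                 as.integer(groups), x$rq)
    list(if (x$rq) bw$dx else NULL,
         if (gamma$rq) bw$dgamma else NULL,
         if (beta$rq) bw$dbeta else NULL)
  })
}

# Batch normalization (per channel over batch and space).  `state` is an
# environment holding running_mean / running_var; updated when training.
t_batchnorm <- function(x, gamma, beta, state, training = TRUE,
                        momentum = 0.1, eps = 1e-5) {
  x <- as_tn(x); gamma <- as_tn(gamma); beta <- as_tn(beta)
  d <- dim(x$v)
  B <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  n <- B * H * W
  M <- matrix(aperm(x$v, c(1, 3, 4, 2)), n, C)
  if (training) {
    mu <- colMeans(M)
    va <- colMeans(M * M) - mu * mu
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var  <- (1 - momentum) * state$running_var + momentum * va * n / max(1, n - 1)
  } else {
    mu <- state$running_mean
    va <- state$running_var
  }
  istd <- 1 / sqrt(va + eps)
  xh <- (M - rep(mu, each = n)) * rep(istd, each = n)
  Y <- xh * rep(as.numeric(gamma$v), each = n) + rep(as.numeric(beta$v), each = n)
  out <- aperm(array(Y, c(B, H, W, C)), c(1, 4, 2, 3))
  ag_node(out, list(x, gamma, beta), function(g) {
    G <- matrix(aperm(g, c(1, 3, 4, 2)), n, C)
    dgam <- if (gamma$rq) colSums(G * xh) else NULL
    dbet <- if (beta$rq) colSums(G) else NULL
    dx <- NULL
    if (x$rq) {
      dxh <- G * rep(as.numeric(gamma$v), each = n)
      if (training) {
        m1 <- colMeans(dxh)
        m2 <- colMeans(dxh * xh)
        dM <- (dxh - rep(m1, each = n) - xh * rep(m2, each = n)) * rep(istd, each = n)
      } else {
        dM <- dxh * rep(istd, each = n)
      }
      dx <- aperm(array(dM, c(B, H, W, C)), c(1, 4, 2, 3))
    }
    list(dx, dgam, dbet)
  })
}

# Interpolation matrix (Hout x Hin) for 1-D bilinear resize with the
# half-pixel-center convention (align_corners = FALSE).
bilinear_matrix <- function(Hout, Hin) {
  U <- matrix(0, Hout, Hin)
  sc <- Hin / Hout
  for (o in seq_len(Hout)) {
    c0 <- (o - 0.5) * sc - 0.5           # 0-based source coordinate
    lo <- floor(c0)
    w_hi <- c0 - lo
    i_lo <- min(max(lo, 0), Hin - 1) + 1
    i_hi <- min(max(lo + 1, 0), Hin - 1) + 1
    U[o, i_lo] <- U[o, i_lo] + (1 - w_hi)
    U[o, i_hi] <- U[o, i_hi] + w_hi
  }
  U
}

apply_sep_resize <- function(v, Uh, Uw) {
  d <- dim(v)                             # (B,C,H,W)
  a <- aperm(v, c(3, 4, 1, 2))            # (H,W,B,C)
  y1 <- Uh %*% matrix(a, d[3], d[4] * d[1] * d[2])
  Ho <- nrow(Uh)
  a2 <- aperm(array(y1, c(Ho, d[4], d[1], d[2])), c(2, 1, 3, 4))  # (W,Ho,B,C)
  y2 <- Uw %*% matrix(a2, d[4], Ho * d[1] * d[2])
  Wo <- nrow(Uw)
  aperm(array(y2, c(Wo, Ho, d[1], d[2])), c(3, 4, 2, 1))          # (B,C,Ho,Wo)
}

# Bilinear upsampling by an integer factor (default 2).
t_upsample_bilinear <- function(x, factor = 2L) {
  x <- as_tn(x)
  d <- dim(x$v)
  Uh <- bilinear_matrix(d[3] * factor, d[3])
  Uw <- bilinear_matrix(d[4] * factor, d[4])
  out <- apply_sep_resize(x$v, Uh, Uw)
  ag_node(out, list(x), function(g) list(apply_sep_resize(g, t(Uh), t(Uw))))
}
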