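# Minimal reverse-mode automatic differentiation over dense R arrays.
#
# Every feature map is a rank-4 array laid out (batch, channels, height,
# width).  A "tensor" is an environment holding a value `v`, an accumulated
# gradient `g`, and -- for nodes created while the tape is recording -- the
# parent tensors and a backward closure.  The tape is creation-ordered, hence
# already topologically sorted; backpropagation walks it in reverse.

.ag <- new.env(parent = emptyenv())
.ag$on <- FALSE
.ag$tape <- vector("list", 4096L)
.ag$n <- 0L

#' Create a tensor
#'
#' Wraps a numeric array (or scalar/vector) as an autodiff tensor.  Leaf
#' tensors created with `requires_grad = TRUE` act as trainable parameters:
#' [ag_backward()] accumulates gradients into their `g` slot.
#'
#' @param value numeric array/vector/scalar.
#' @param requires_grad logical; should gradients be accumulated here?
#' @return an object of class `ltp_tensor` (an environment).
#' @export
tn_tensor <- function(value, requires_grad = FALSE) {
  e <- new.env(parent = emptyenv())
  e$v <- value
  e$g <- NULL
  e$rq <- requires_grad
  e$leaf <- TRUE
  class(e) <- "ltp_tensor"
  e
}

#' @export
print.ltp_tensor <- function(x, ...) {
  d <- dim(x$v)
  cat("<ltp_tensor ", if (is.null(d)) length(x$v) else paste(d, collapse = "x"),
      if (x$rq) " grad" else "", ">\n", sep = "")
  invisible(x)
}

is_tn <- function(x) inherits(x, "ltp_tensor")
as_tn <- function(x) if (is_tn(x)) x else tn_tensor(x)

#' Extract the value of a tensor
#' @param x tensor or plain numeric.
#' @return the underlying numeric array.
#' @export
tn_value <- function(x) if (is_tn(x)) x$v else x

tape_push <- function(node) {
  n <- .ag$n + 1L
  if (n > length(.ag$tape)) .ag$tape <- c(.ag$tape, vector("list", length(.ag$tape)))
  .ag$tape[[n]] <- node
  .ag$n <- n
  invisible(node)
}

tape_reset <- function() {
  if (.ag$n > 0L) .ag$tape[seq_len(.ag$n)] <- list(NULL)
  .ag$n <- 0L
  invisible(NULL)
}

#' Evaluate an expression with gradient recording enabled
#'
#' Resets the tape, records every differentiable operation performed while
#' evaluating `expr`, and leaves the tape in place so [ag_backward()] can be
#' called on the result.
#' @param expr expression producing (typically) a scalar loss tensor.
#' @export
ag_record <- function(expr) {
  tape_reset()
  .ag$on <- TRUE
  on.exit(.ag$on <- FALSE)
  expr
}

#' Evaluate an expression with gradient recording disabled
#' @param expr expression.
#' @export
ag_no_grad <- function(expr) {
  old <- .ag$on
  .ag$on <- FALSE
  on.exit(.ag$on <- old)
  expr
}

# Create a non-leaf node.  `bk` maps the node's output gradient to a list of
# parent gradients (NULL entries for parents that do not require grad).
ag_node <- function(value, parents, bk) {
  rq <- any(vapply(parents, function(p) is_tn(p) && p$rq, logical(1)))
  if (!.ag$on || !rq) return(tn_tensor(value))
  e <- tn_tensor(value)
  e$rq <- TRUE
  e$leaf <- FALSE
  e$ps <- parents
  e$bk <- bk
  tape_push(e)
  e
}

#' Backpropagate from a scalar tensor
#'
#' Seeds the output gradient with 1 and walks the recorded tape in reverse,
#' accumulating gradients into every reachable leaf tensor that requires
#' them.
#' @param root scalar tensor produced inside [ag_record()].
#' @export
ag_backward <- function(root) {
  if (!is_tn(root)) stop("ag_backward() needs a tensor")
  if (length(root$v) != 1L) stop("ag_backward() expects a scalar root")
  root$g <- if (is.null(dim(root$v))) 1 else array(1, dim(root$v))
  for (i in rev(seq_len(.ag$n))) {
    nd <- .ag$tape[[i]]
    if (is.null(nd$g)) next
    gs <- nd$bk(nd$g)
    ps <- nd$ps
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      if (is_tn(p) && p$rq && !is.null(gs[[j]])) {
        p$g <- if (is.null(p$g)) gs[[j]] else p$g + gs[[j]]
      }
    }
    if (!nd$leaf) nd$g <- NULL   # free intermediate grads eagerly
  }
  invisible(NULL)
}

# ---- broadcasting helpers ---------------------------------------------------

# Expand `x` (rank-4, some extents 1) to `td` by index replication.
bcast4 <- function(x, td) {
  d <- dim(x)
  if (identical(d, td)) return(x)
  x[if (d[1] == td[1]) seq_len(d[1]) else rep(1L, td[1]),
    if (d[2] == td[2]) seq_len(d[2]) else rep(1L, td[2]),
    if (d[3] == td[3]) seq_len(d[3]) else rep(1L, td[3]),
    if (d[4] == td[4]) seq_len(d[4]) else rep(1L, td[4]), drop = FALSE]
}

# Sum `g` (dims `gd`) down to shape `sd` (entries of sd are gd or 1).
reduce_to4 <- function(g, sd) {
  gd <- dim(g)
  if (identical(gd, sd)) return(g)
  red <- which(sd == 1L & gd > 1L)
  keep <- setdiff(1:4, red)
  a <- aperm(g, c(keep, red))
  dim(a) <- c(prod(gd[keep]), prod(gd[red]))
  out <- rowSums(a)
  dim(out) <- sd
  out
}

# ---- elementwise arithmetic -------------------------------------------------

# Promote a dimensionless scalar to a rank-4 singleton so the broadcasting
# binary ops accept plain numeric constants.
as4 <- function(v) {
  if (is.null(dim(v)) && length(v) == 1L) array(v, c(1L, 1L, 1L, 1L)) else v
}

# a + b with rank-4 broadcasting (extents of 1 broadcast).
t_add <- function(a, b) {
  a <- as_tn(a); b <- as_tn(b)
  da <- dim(as4(a$v)); db <- dim(as4(b$v))
  td <- pmax(da, db)
  av <- if (identical(da, td)) a$v else bcast4(as4(a$v), td)
  bv <- if (identical(db, td)) b$v else bcast4(as4(b$v), td)
  ag_node(av + bv, list(a, b), function(g) {
    list(if (a$rq) reduce_to4(g, da) else NULL,
         if (b$rq) reduce_to4(g, db) else NULL)
  })
}

t_sub <- function(a, b) {
  a <- as_tn(a); b <- as_tn(b)
  da <- dim(as4(a$v)); db <- dim(as4(b$v))
  td <- pmax(da, db)
  av <- if (identical(da, td)) a$v else bcast4(as4(a$v), td)
  bv <- if (identical(db, td)) b$v else bcast4(as4(b$v), td)
  ag_node(av - bv, list(a, b), function(g) {
    list(if (a$rq) reduce_to4(g, da) else NULL,
         if (b$rq) -reduce_to4(g, db) else NULL)
  })
}

# a * b with rank-4 broadcasting (used for channel/spatial attention gates).
t_mul <- function(a, b) {
  a <- as_tn(a); b <- as_tn(b)
  da <- dim(as4(a$v)); db <- dim(as4(b$v))
  td <- pmax(da, db)
  av <- if (identical(da, td)) a$v else bcast4(as4(a$v), td)
  bv <- if (identical(db, td)) b$v else bcast4(as4(b$v), td)
  ag_node(av * bv, list(a, b), function(g) {
    list(if (a$rq) reduce_to4(g * bv, da) else NULL,
         if (b$rq) reduce_to4(g * av, db) else NULL)
  })
}

t_scale <- function(a, s) {  # s: plain scalar
  a <- as_tn(a)
  ag_node(a$v * s, list(a), function(g) list(g * s))
}

# ---- activations ------------------------------------------------------------

t_relu <- function(a) {
  a <- as_tn(a)
  m <- a$v > 0
  ag_node(a$v * m, list(a), function(g) list(g * m))
}

t_sigmoid <- function(a) {
  a <- as_tn(a)
  s <- 1 / (1 + exp(-a$v))
  ag_node(s, list(a), function(g) list(g * s * (1 - s)))
}

t_gelu <- function(a) {  # exact Gaussian error linear unit
  a <- as_tn(a)
  ph <- stats::pnorm(a$v)
  ag_node(a$v * ph, list(a), function(g) list(g * (ph + a$v * stats::dnorm(a$v))))
}

softplus_ <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

t_softplus <- function(a) {
  a <- as_tn(a)
  ag_node(softplus_(a$v), list(a), function(g) list(g / (1 + exp(-a$v))))
}

# ---- reductions and pooling -------------------------------------------------

t_mean_all <- function(a) {
  a <- as_tn(a)
  n <- length(a$v)
  ag_node(mean(a$v), list(a), function(g) list(array(as.numeric(g) / n, dim(a$v))))
}

# Global average pooling (B,C,H,W) -> (B,C,1,1).
t_gap <- function(a) {
  a <- as_tn(a)
  d <- dim(a$v)
  m <- rowMeans(matrix(a$v, d[1] * d[2], d[3] * d[4]))
  ag_node(array(m, c(d[1], d[2], 1L, 1L)), list(a), function(g) {
    list(array(rep(as.vector(g) / (d[3] * d[4]), times = d[3] * d[4]), d))
  })
}

# Channel-wise max and mean maps, concatenated: (B,C,H,W) -> (B,2,H,W).
# Used by the spatial-attention gate.  Max ties route the gradient to the
# first maximal channel.
t_chan_maxmean <- function(a) {
  a <- as_tn(a)
  d <- dim(a$v)
  B <- d[1]; C <- d[2]; S <- d[3] * d[4]
  m <- matrix(aperm(a$v, c(2, 1, 3, 4)), C, B * S)   # channels x (B*S)
  imax <- max.col(t(m), ties.method = "first")
  mx <- m[cbind(imax, seq_len(B * S))]
  mn <- colMeans(m)
  out <- array(0, c(B, 2L, d[3], d[4]))
  out[, 1L, , ] <- array(mx, c(B, d[3], d[4]))
  out[, 2L, , ] <- array(mn, c(B, d[3], d[4]))
  ag_node(out, list(a), function(g) {
    gmx <- as.vector(g[, 1L, , ])          # length B*S, ordered like m's cols
    gmn <- as.vector(g[, 2L, , ])
    dm <- matrix(rep(gmn / C, each = C), C, B * S)
    dm[cbind(imax, seq_len(B * S))] <- dm[cbind(imax, seq_len(B * S))] + gmx
    list(aperm(array(dm, c(C, B, d[3], d[4])), c(2, 1, 3, 4)))
  })
}

# ---- linear combination of three maps with a coefficient vector -------------

# out = c[1]*f1 + c[2]*f2 + c[3]*f3 ; `coef` is a length-3 tensor.
t_lincomb3 <- function(f1, f2, f3, coef) {
  f1 <- as_tn(f1); f2 <- as_tn(f2); f3 <- as_tn(f3); coef <- as_tn(coef)
  cv <- as.numeric(coef$v)
  ag_node(cv[1] * f1$v + cv[2] * f2$v + cv[3] * f3$v, list(f1, f2, f3, coef),
          function(g) {
            list(if (f1$rq) g * cv[1] else NULL,
                 if (f2$rq) g * cv[2] else NULL,
                 if (f3$rq) g * cv[3] else NULL,
                 if (coef$rq) c(sum(g * f1$v), sum(g * f2$v), sum(g * f3$v)) else NULL)
          })
}

# Softmax over a short vector (fusion coefficient logits).
t_softmax_vec <- function(a) {
  a <- as_tn(a)
  z <- as.numeric(a$v)
  s <- exp(z - max(z)); s <- s / sum(s)
  ag_node(s, list(a), function(g) {
    g <- as.numeric(g)
    list(s * (g - sum(g * s)))
  })
}
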