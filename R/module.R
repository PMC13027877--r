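# Lightweight module system: a module is an environment with `kind`, a named
# list of parameter tensors `params`, a named list of child modules
# `children`, optional mutable `state` (e.g. batch-norm running statistics),
# and a `forward` closure.  Parameters are collected recursively for the
# optimizer and for checkpointing.

new_module <- function(kind, params = list(), children = list(), state = NULL) {
  e <- new.env(parent = emptyenv())
  e$kind <- kind
  e$params <- params
  e$children <- children
  e$state <- state
  class(e) <- c(paste0("ltp_", kind), "ltp_module")
  e
}

#' Collect all trainable parameters of a module
#'
#' @param mod a module (e.g. a model built by [ltpnet()]).
#' @param prefix internal; name prefix for nesting.
#' @return named list of parameter tensors, depth-first.
#' @export
module_parameters <- function(mod, prefix = "") {
  out <- list()
  for (nm in names(mod$params)) out[[paste0(prefix, nm)]] <- mod$params[[nm]]
  for (nm in names(mod$children)) {
    out <- c(out, module_parameters(mod$children[[nm]], paste0(prefix, nm, ".")))
  }
  out
}

#' Count trainable scalars in a module
#' @param mod a module.
#' @return integer count.
#' @export
module_n_params <- function(mod) {
  sum(vapply(module_parameters(mod), function(p) length(p$v), numeric(1)))
}

# Zero every accumulated gradient.
module_zero_grad <- function(mod) {
  for (p in module_parameters(mod)) p$g <- NULL
  invisible(mod)
}

# Apply `fn(name, tensor)` over all parameters (used by tests to freeze
# weights and by checkpointing).
module_map_params <- function(mod, fn) {
  ps <- module_parameters(mod)
  for (nm in names(ps)) fn(nm, ps[[nm]])
  invisible(mod)
}

# Export / import flat numeric state (checkpoints are plain lists).
module_state_dict <- function(mod) {
  lapply(module_parameters(mod), function(p) p$v)
}

module_load_state_dict <- function(mod, sd) {
  ps <- module_parameters(mod)
  if (!setequal(names(ps), names(sd))) stop("checkpoint/model parameter mismatch")
  for (nm in names(ps)) {
    if (!identical(dim(ps[[nm]]$v), dim(sd[[nm]])) &&
        length(ps[[nm]]$v) != length(sd[[nm]])) {
      stop("checkpoint/model shape mismatch at ", nm)
    }
    v <- sd[[nm]]
    if (!is.null(dim(ps[[nm]]$v))) dim(v) <- dim(ps[[nm]]$v)
    ps[[nm]]$v <- v
  }
  invisible(mod)
}

# ---- parameter initialization ----------------------------------------------

# Kaiming-style normal init for conv weights; biases start at zero so the
# all-zero-input identities hold exactly at initialization.
init_conv_w <- function(cin, k, cout) {
  sd <- sqrt(2 / (cin * k * k))
  tn_tensor(array(stats::rnorm(cin * k * k * cout, 0, sd), c(cin, k, k, cout)),
            requires_grad = TRUE)
}

init_vec <- function(n, value = 0) tn_tensor(rep(value, n), requires_grad = TRUE)

# Dense conv layer module.
new_conv <- function(cin, cout, k = 3L, stride = 1L, pad = NULL, bias = TRUE) {
  p <- list(w = init_conv_w(cin, k, cout))
  if (bias) p$b <- init_vec(cout, 0)
  m <- new_module("conv", params = p)
  m$cin <- cin; m$cout <- cout; m$k <- k; m$stride <- stride; m$pad <- pad
  m$forward <- function(x) t_conv2d(x, m$params$w, m$params$b, stride = m$stride, pad = m$pad)
  m
}

new_dwconv <- function(C, k = 3L, bias = TRUE) {
  sd <- sqrt(2 / (k * k))
  p <- list(w = tn_tensor(array(stats::rnorm(C * k * k, 0, sd), c(C, k, k)),
                          requires_grad = TRUE))
  if (bias) p$b <- init_vec(C, 0)
  m <- new_module("dwconv", params = p)
  m$forward <- function(x) t_dwconv2d(x, m$params$w, m$params$b)
  m
}

# Largest divisor of `C` that is <= `g` (group-norm groups must divide the
# channel count; the default of 8 is clamped per layer).
fit_groups <- function(C, g) {
  g <- max(1L, min(as.integer(g), as.integer(C)))
  while (C %% g != 0L) g <- g - 1L
  g
}

new_groupnorm <- function(C, groups = 8L, strict = FALSE) {
  if (strict && C %% groups != 0L) {
    stop(sprintf("group count %d does not divide %d channels", groups, C))
  }
  groups <- fit_groups(C, groups)
  m <- new_module("groupnorm",
                  params = list(gamma = init_vec(C, 1), beta = init_vec(C, 0)))
  m$groups <- groups
  m$forward <- function(x) t_groupnorm(x, m$params$gamma, m$params$beta, m$groups)
  m
}

new_batchnorm <- function(C) {
  st <- new.env(parent = emptyenv())
  st$running_mean <- rep(0, C)
  st$running_var <- rep(1, C)
  m <- new_module("batchnorm",
                  params = list(gamma = init_vec(C, 1), beta = init_vec(C, 0)),
                  state = st)
  m$training <- TRUE
  m$forward <- function(x) t_batchnorm(x, m$params$gamma, m$params$beta, m$state,
                                       training = m$training)
  m
}

# Put every batch-norm submodule into train/eval mode.
module_set_training <- function(mod, training = TRUE) {
  if (mod$kind == "batchnorm") mod$training <- training
  for (ch in mod$children) module_set_training(ch, training)
  invisible(mod)
}
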