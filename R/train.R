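# Training: AdamW with a cosine-annealed learning rate fixed a priori,
# hybrid BCE+Dice loss, optional flip/right-angle-rotation augmentation, and
# evaluation that aggregates a dataset-level confusion matrix.

#' Training configuration
#'
#' @param lr initial learning rate (cosine-annealed).
#' @param lr_min final learning rate of the cosine schedule.
#' @param weight_decay decoupled AdamW weight decay.
#' @param batch_size minibatch size (clamped to the dataset size).
#' @param steps total optimizer steps; the schedule is fully determined
#'   before training starts.
#' @param augment apply random flip/rotation augmentation.
#' @param seed RNG seed controlling batching, augmentation and any model
#'   initialization performed by the caller.
#' @param loss a [loss_weights()].
#' @return a `train_config` list.
#' @export
train_config <- function(lr = 1e-3, lr_min = 1e-5, weight_decay = 1e-2,
                         batch_size = 32L, steps = 300L, augment = TRUE,
                         seed = 1L, loss = loss_weights()) {
  if (lr <= 0 || batch_size < 1) stop("configuration error: lr > 0 and batch_size >= 1 required")
  structure(list(lr = lr, lr_min = lr_min, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size), steps = as.integer(steps),
                 augment = isTRUE(augment), seed = as.integer(seed), loss = loss),
            class = "train_config")
}

#' Cosine-annealed learning rate
#'
#' Pure function of the step index: `lr_min + (lr0 - lr_min) * (1 +
#' cos(pi * step / total)) / 2` with `step` counted from 0; the final
#' scheduled step returns exactly `lr_min`.
#'
#' @param step 0-based step index.
#' @param total total number of steps.
#' @param lr0,lr_min initial and final learning rates.
#' @export
cosine_lr <- function(step, total, lr0, lr_min = 0) {
  lr_min + 0.5 * (lr0 - lr_min) * (1 + cos(pi * pmin(step, total) / total))
}

adamw_new <- function(params, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 1e-2) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(p) array(0, dim(p$v) %||% length(p$v)))
  st$v <- lapply(params, function(p) array(0, dim(p$v) %||% length(p$v)))
  st$t <- 0L
  st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps; st$wd <- weight_decay
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adamw_step <- function(st, params, lr) {
  st$t <- st$t + 1L
  bc1 <- 1 - st$beta1^st$t
  bc2 <- 1 - st$beta2^st$t
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$g
    if (is.null(g)) next
    st$m[[i]] <- st$beta1 * st$m[[i]] + (1 - st$beta1) * g
    st$v[[i]] <- st$beta2 * st$v[[i]] + (1 - st$beta2) * g * g
    upd <- (st$m[[i]] / bc1) / (sqrt(st$v[[i]] / bc2) + st$eps)
    p$v <- p$v - lr * (upd + st$wd * p$v)
  }
  invisible(st)
}

normalize_batch <- function(x, norm) {
  for (c in seq_len(dim(x)[2])) x[, c, , ] <- (x[, c, , ] - norm$mean[c]) / norm$sd[c]
  x
}

#' Train a model on a list of image/mask pairs
#'
#' Runs `steps` AdamW updates of the hybrid BCE+Dice loss under the cosine
#' schedule, re-asserting the TPFF simplex constraint after every step.
#' Per-channel normalization statistics are computed from the training pairs
#' and stored on the model (they travel with checkpoints).
#'
#' @param model module from [ltpnet()].
#' @param pairs list of pairs from [load_pair()] / [generate_lesion_image()]
#'   (each a list with `image` (H,W,3) and `mask` (H,W)).
#' @param cfg a [train_config()].
#' @param verbose print a line every 25 steps.
#' @return list with `loss` (per-step trace), `lr` (per-step rate) and
#'   `coeff_sum` (per-step TPFF coefficient sums), invisibly; the model is
#'   updated in place.
#' @export
train_ltpnet <- function(model, pairs, cfg = train_config(), verbose = FALSE) {
  if (length(pairs) == 0) stop("configuration error: empty dataset")
  set.seed(cfg$seed)
  n <- length(pairs)
  bs <- min(cfg$batch_size, n)
  all_imgs <- vapply(pairs, function(p) p$image, FUN.VALUE = pairs[[1]]$image)
  norm <- list(mean = numeric(3), sd = numeric(3))
  for (c in 1:3) {
    ch <- all_imgs[, , c, ]
    norm$mean[c] <- mean(ch)
    norm$sd[c] <- max(stats::sd(ch), 1e-3)
  }
  model$norm <- norm
  params <- module_parameters(model)
  opt <- adamw_new(params, weight_decay = cfg$weight_decay)
  module_set_training(model, TRUE)
  loss_trace <- numeric(cfg$steps)
  lr_trace <- numeric(cfg$steps)
  coeff_sum <- numeric(cfg$steps)
  for (step in seq_len(cfg$steps)) {
    idx <- if (bs >= n) seq_len(n) else sample.int(n, bs)
    bp <- pairs[idx]
    if (cfg$augment) bp <- lapply(bp, function(p) augment_pair(p$image, p$mask))
    b <- pairs_to_batch(bp)
    xb <- normalize_batch(b$x, norm)
    lr <- cosine_lr(step - 1L, cfg$steps, cfg$lr, cfg$lr_min)
    module_zero_grad(model)
    loss <- ag_record({
      probs <- model$forward(xb)
      t_hybrid_loss(probs, b$y, cfg$loss$lambda1, cfg$loss$lambda2)
    })
    lv <- as.numeric(tn_value(loss))
    if (!is.finite(lv)) {
      stop(sprintf("training aborted: non-finite loss at step %d (lr=%.2e)", step, lr))
    }
    ag_backward(loss)
    tape_reset()
    adamw_step(opt, params, lr)
    loss_trace[step] <- lv
    lr_trace[step] <- lr
    cs <- if (length(model$tpffs) > 0) {
      s <- vapply(model$tpffs, function(tp) sum(tpff_coefficients(tp)), numeric(1))
      if (any(abs(s - 1) > 1e-8)) stop("TPFF simplex invariant violated during training")
      mean(s)
    } else NA_real_
    coeff_sum[step] <- cs
    if (verbose && step %% 25L == 0L) {
      message(sprintf("step %4d  loss %.4f  lr %.2e", step, lv, lr))
    }
  }
  invisible(list(loss = loss_trace, lr = lr_trace, coeff_sum = coeff_sum))
}

#' Evaluate a model on image/mask pairs
#'
#' Predicts at the given threshold (positive iff probability >= threshold),
#' aggregates pixel confusion counts over the whole set, and computes the
#' metric report plus PR/ROC curves on the raw probabilities.
#'
#' @param model trained module from [ltpnet()].
#' @param pairs list of pairs (see [train_ltpnet()]).
#' @param threshold binarization threshold in (0, 1).
#' @return list with `metrics` ([segmentation_metrics()] plus `auc_pr`,
#'   `auc_roc`), `counts`, `curves` and `per_image` Dice values.
#' @export
evaluate_ltpnet <- function(model, pairs, threshold = 0.5) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop("configuration error: threshold must lie strictly in (0, 1)")
  }
  b <- pairs_to_batch(pairs)
  xb <- if (!is.null(model$norm)) normalize_batch(b$x, model$norm) else b$x
  module_set_training(model, FALSE)
  on.exit(module_set_training(model, TRUE))
  probs <- ag_no_grad(tn_value(model$forward(xb)))
  pred <- (probs >= threshold) * 1L
  cc <- confusion_counts(pred, b$y)
  met <- segmentation_metrics(cc)
  curves <- pr_roc(as.vector(probs), as.vector(b$y))
  per_image <- vapply(seq_len(dim(probs)[1]), function(i) {
    p <- pred[i, , , ]; g <- b$y[i, , , ]
    2 * sum(p * g) / max(1, sum(p) + sum(g))
  }, numeric(1))
  list(metrics = c(unclass(met), list(auc_pr = curves$auc_pr, auc_roc = curves$auc_roc)),
       counts = cc, curves = curves, per_image_dsc = per_image)
}

#' Save a checkpoint (weights + configs + normalization statistics)
#' @param model module from [ltpnet()].
#' @param path output file.
#' @param train_cfg optional [train_config()] to embed.
#' @export
save_checkpoint <- function(model, path, train_cfg = NULL) {
  saveRDS(list(state = module_state_dict(model), cfg = model$cfg,
               norm = model$norm, train_cfg = train_cfg,
               format = "ltpnet-checkpoint-1"), path)
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#' @param path checkpoint file.
#' @return a rebuilt model with restored weights.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "ltpnet-checkpoint-1")) {
    stop("versioning error: not a compatible checkpoint")
  }
  model <- ltpnet(ck$cfg, seed = 0L)
  module_load_state_dict(model, ck$state)
  model$norm <- ck$norm
  model
}
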