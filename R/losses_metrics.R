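# Hybrid BCE + Dice training loss and the evaluation metrics: foreground
# IoU (mIoU), Dice, accuracy, specificity, sensitivity, and PR/ROC curves
# with trapezoidal AUCs.  mIoU is defined as the lesion-class IoU on the
# dataset-aggregated confusion matrix, the reading under which the identity
# IoU = DSC / (2 - DSC) holds exactly.

#' Loss weights
#' @param lambda1 weight of the BCE term (default 1).
#' @param lambda2 weight of the Dice term (default 1).
#' @return a `loss_weights` list.
#' @export
loss_weights <- function(lambda1 = 1, lambda2 = 1) {
  if (!is.finite(lambda1) || !is.finite(lambda2) || lambda1 < 0 || lambda2 < 0) {
    stop("loss weights must be finite and nonnegative")
  }
  structure(list(lambda1 = lambda1, lambda2 = lambda2), class = "loss_weights")
}

# Differentiable hybrid loss primitive.
t_hybrid_loss <- function(probs, gt, l1 = 1, l2 = 1, eps = 1e-7) {
  probs <- as_tn(probs)
  gv <- tn_value(gt)
  pv <- probs$v
  if (!identical(dim(pv), dim(gv))) stop("shape error: probs/gt extents differ")
  n <- length(pv)
  pc <- pmin(pmax(pv, eps), 1 - eps)
  bce <- -mean(gv * log(pc) + (1 - gv) * log(1 - pc))
  sp <- sum(pv); sg <- sum(gv); spg <- sum(pv * gv)
  dice <- 1 - (2 * spg + eps) / (sp + sg + eps)
  ag_node(l1 * bce + l2 * dice, list(probs), function(g) {
    g <- as.numeric(g)
    dbce <- (pc - gv) / (pc * (1 - pc)) / n
    den <- sp + sg + eps
    ddice <- -(2 * gv * den - (2 * spg + eps)) / (den * den)
    list(g * (l1 * dbce + l2 * ddice))
  })
}

#' Hybrid BCE + Dice segmentation loss
#'
#' `lambda1 * L_bce + lambda2 * L_dice`, with
#' `L_dice = 1 - (2*sum(p*g) + eps) / (sum(p) + sum(g) + eps)` and `L_bce`
#' the mean binary cross-entropy with probabilities clamped to
#' `[eps, 1 - eps]`.
#'
#' @param probs probability map, array or tensor, values in `[0, 1]`.
#' @param gt binary ground-truth mask with matching extents.
#' @param weights a [loss_weights()].
#' @param eps clamping / smoothing constant.
#' @return a numeric scalar (or a scalar tensor when `probs` is a tensor
#'   recorded on the tape).
#' @export
hybrid_loss <- function(probs, gt, weights = loss_weights(), eps = 1e-7) {
  out <- t_hybrid_loss(probs, gt, weights$lambda1, weights$lambda2, eps)
  if (is_tn(probs) && probs$rq) out else as.numeric(tn_value(out))
}

#' Aggregate a pixel confusion matrix
#'
#' @param pred,gt binary arrays (0/1 or logical) with matching extents.
#' @return a `confusion_counts` list with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(pred, gt) {
  p <- as.numeric(tn_value(pred)); g <- as.numeric(tn_value(gt))
  if (length(p) != length(g)) stop("shape error: extents differ")
  if (!all(p %in% c(0, 1)) || !all(g %in% c(0, 1))) {
    stop("input error: confusion_counts expects strictly binary inputs")
  }
  structure(list(tp = sum(p == 1 & g == 1), fp = sum(p == 1 & g == 0),
                 fn = sum(p == 0 & g == 1), tn = sum(p == 0 & g == 0)),
            class = "confusion_counts")
}

#' Derive segmentation metrics from confusion counts
#'
#' `acc = (tp+tn)/total`, `sen = tp/(tp+fn)`, `spe = tn/(tn+fp)`,
#' `dsc = 2tp/(2tp+fp+fn)`, `miou = tp/(tp+fp+fn)` (foreground IoU).
#'
#' @param counts a `confusion_counts` list (or plain list with tp/fp/fn/tn).
#' @return a `metrics_report` list with the five fractions.
#' @export
segmentation_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  if (tp + fn == 0) stop("undefined metric: sensitivity (no positive pixels in gt)")
  if (tn + fp == 0) stop("undefined metric: specificity (no negative pixels in gt)")
  total <- tp + fp + fn + tn
  structure(list(acc = (tp + tn) / total,
                 sen = tp / (tp + fn),
                 spe = tn / (tn + fp),
                 dsc = 2 * tp / (2 * tp + fp + fn),
                 miou = tp / (tp + fp + fn)),
            class = "metrics_report")
}

#' Precision-recall and ROC curves with trapezoidal AUCs
#'
#' Sweeps all unique score values as thresholds (prediction positive iff
#' score >= threshold).  The ROC AUC equals the Mann-Whitney statistic
#' (ties counted 1/2).
#'
#' @param scores numeric scores / probabilities.
#' @param labels binary labels with matching length.
#' @return list with `roc` and `pr` data frames (`threshold`, `tpr`/`fpr`,
#'   `precision`/`recall`) and scalars `auc_roc`, `auc_pr`.
#' @export
pr_roc <- function(scores, labels) {
  s <- as.numeric(tn_value(scores)); y <- as.numeric(tn_value(labels))
  if (length(s) != length(y)) stop("shape error: lengths differ")
  P <- sum(y == 1); N <- sum(y == 0)
  if (P == 0 || N == 0) stop("undefined curve: ground truth contains a single class")
  o <- order(s, decreasing = TRUE)
  s <- s[o]; y <- y[o]
  ctp <- cumsum(y == 1); cfp <- cumsum(y == 0)
  last <- which(c(s[-1] != s[-length(s)], TRUE))   # last index of each tie group
  thr <- s[last]
  tp <- ctp[last]; fp <- cfp[last]
  tpr <- c(0, tp / P); fpr <- c(0, fp / N)
  auc_roc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  prec <- tp / (tp + fp)
  rec <- tp / P
  recall <- c(0, rec); precision <- c(1, prec)
  auc_pr <- sum(diff(recall) * (utils::head(precision, -1) + utils::tail(precision, -1)) / 2)
  list(roc = data.frame(threshold = c(Inf, thr), tpr = tpr, fpr = fpr),
       pr = data.frame(threshold = c(Inf, thr), precision = precision, recall = recall),
       auc_roc = auc_roc, auc_pr = auc_pr)
}
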