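# Hybrid loss closed forms, confusion-matrix bookkeeping, the metric
# identities, and AUC versus an O(n^2) pairwise oracle.

test_that("hybrid loss: perfect prediction, ln(2) BCE, additivity of terms", {
  set.seed(1)
  gt <- array(rbinom(64, 1, 0.4), c(1, 1, 8, 8))
  expect_lt(hybrid_loss(gt + 0, gt), 1e-3)                  # probs == gt

  half <- array(0.5, dim(gt))
  w_bce <- loss_weights(lambda1 = 1, lambda2 = 0)
  expect_equal(hybrid_loss(half, gt, w_bce), log(2), tolerance = 1e-9)
  gt2 <- array(rbinom(64, 1, 0.8), c(1, 1, 8, 8))
  expect_equal(hybrid_loss(half, gt2, w_bce), log(2), tolerance = 1e-9)

  probs <- array(runif(64, 0.05, 0.95), dim(gt))
  b <- hybrid_loss(probs, gt, loss_weights(1, 0))
  d <- hybrid_loss(probs, gt, loss_weights(0, 1))
  expect_equal(hybrid_loss(probs, gt), b + d, tolerance = 1e-12)
  expect_error(hybrid_loss(array(0.5, c(1, 1, 2, 2)), gt), "shape error")
})

test_that("hybrid loss is nonnegative and decreases toward the ground truth", {
  set.seed(2)
  gt <- array(rbinom(100, 1, 0.5), c(1, 1, 10, 10))
  start <- array(runif(100, 0.2, 0.8), dim(gt))
  prev <- Inf
  for (lam in seq(0, 1, by = 0.25)) {
    probs <- (1 - lam) * start + lam * (0.999 * gt + 0.0005)
    l <- hybrid_loss(probs, gt)
    expect_gte(l, 0)
    expect_lt(l, prev)
    prev <- l
  }
})

test_that("confusion counts: exact bookkeeping and binary validation", {
  gt <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  pred <- c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)   # 3 tp, 1 fp, 1 fn, 5 tn
  cc <- confusion_counts(pred, gt)
  expect_equal(unclass(cc)[c("tp", "fp", "fn", "tn")],
               list(tp = 3, fp = 1, fn = 1, tn = 5))
  same <- confusion_counts(gt, gt)
  expect_equal(same$fp + same$fn, 0)
  flip <- confusion_counts(1 - gt, gt)
  expect_equal(flip$tp + flip$tn, 0)
  expect_error(confusion_counts(c(0, 2), c(0, 1)), "binary")
})

test_that("segmentation metrics: hand-computed values and the IoU identity", {
  m <- segmentation_metrics(list(tp = 3, fp = 1, fn = 1, tn = 5))
  expect_equal(m$acc, 0.8)
  expect_equal(m$sen, 0.75)
  expect_equal(round(m$spe, 4), 0.8333)
  expect_equal(m$dsc, 0.75)
  expect_equal(m$miou, 0.6)

  perfect <- segmentation_metrics(list(tp = 7, fp = 0, fn = 0, tn = 3))
  expect_equal(unlist(unclass(perfect)), c(acc = 1, sen = 1, spe = 1, dsc = 1, miou = 1))

  set.seed(3)
  for (i in 1:25) {
    cc <- as.list(rpois(4, 20) + 1)
    names(cc) <- c("tp", "fp", "fn", "tn")
    m <- segmentation_metrics(cc)
    expect_equal(m$miou, m$dsc / (2 - m$dsc), tolerance = 1e-12)
  }
  expect_error(segmentation_metrics(list(tp = 0, fp = 1, fn = 0, tn = 3)), "sensitivity")
  expect_error(segmentation_metrics(list(tp = 2, fp = 0, fn = 1, tn = 0)), "specificity")
})

test_that("pr_roc: separation, chance level, sign reversal, oracle agreement", {
  # perfectly separating scores
  y <- rep(c(1, 0), each = 50)
  s <- c(runif(50, 0.6, 1), runif(50, 0, 0.4))
  expect_equal(pr_roc(s, y)$auc_roc, 1)

  set.seed(4)
  y2 <- rbinom(10000, 1, 0.5)
  s2 <- runif(10000)
  expect_lt(abs(pr_roc(s2, y2)$auc_roc - 0.5), 0.02)

  set.seed(5)
  y3 <- rbinom(150, 1, 0.4)
  s3 <- runif(150)
  a <- pr_roc(s3, y3)$auc_roc
  expect_equal(pr_roc(-s3, y3)$auc_roc, 1 - a, tolerance = 1e-12)

  # trapezoidal AUC == pairwise Mann-Whitney oracle, including ties
  for (i in 1:5) {
    set.seed(10 + i)
    n <- sample(50:200, 1)
    y4 <- rbinom(n, 1, 0.5)
    if (length(unique(y4)) < 2) y4[1:2] <- c(0, 1)
    s4 <- round(runif(n), 2)                 # coarse scores force ties
    expect_equal(pr_roc(s4, y4)$auc_roc, auc_pairwise(s4, y4), tolerance = 1e-12)
  }
  expect_error(pr_roc(runif(5), rep(1, 5)), "single class")
})
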