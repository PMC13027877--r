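# Assembled network: Eq-dataflow invocation counts, probability-map
# contract, inference determinism, threshold semantics, ablation
# robustness, and gradient flow to every parameter.

tiny_model <- function(seed = 3) ltpnet(ltpnet_config("tiny"), seed = seed)

test_that("forward pass invokes ASM 5x, LALGA 8x, TPFF 4x and maps to [0,1]", {
  model <- tiny_model()
  x <- rand_feat(2, 3, 64, 64, seed = 1) * 0.2 + 0.5
  probs <- ag_no_grad(tv(ltpnet_forward(model, x)))
  expect_equal(unname(ltpnet_counts(model)), c(5L, 8L, 4L))
  expect_equal(dim(probs), c(2L, 1L, 64L, 64L))
  expect_true(all(probs >= 0 & probs <= 1))
})

test_that("inference is deterministic (bitwise) and junctions match at 128", {
  model <- tiny_model()
  x <- rand_feat(1, 3, 64, 64, seed = 2)
  a <- ag_no_grad(tv(ltpnet_forward(model, x)))
  b <- ag_no_grad(tv(ltpnet_forward(model, x)))
  expect_identical(a, b)
  # junction extents are asserted inside the forward pass at every level
  x128 <- rand_feat(1, 3, 128, 128, seed = 3)
  p <- ag_no_grad(tv(ltpnet_forward(model, x128)))
  expect_equal(dim(p), c(1L, 1L, 128L, 128L))
  expect_error(ltpnet_forward(model, rand_feat(1, 3, 96, 96, seed = 4)), "divisible")
})

test_that("predict_mask applies the >= threshold rule monotonically", {
  model <- tiny_model()
  x <- rand_feat(2, 3, 64, 64, seed = 5) * 0.2 + 0.5
  m1 <- predict_mask(model, x, threshold = 0.3)
  m2 <- predict_mask(model, x, threshold = 0.7)
  expect_true(all(m2 <= m1))                        # raising threshold shrinks positives
  expect_true(all(m1 %in% c(0L, 1L)))
  expect_error(predict_mask(model, x, threshold = 1.2), "configuration error")
  expect_error(predict_mask(model, x, threshold = 0), "configuration error")
})

test_that("every ablation switch still yields a valid probability map", {
  x <- rand_feat(1, 3, 64, 64, seed = 6) * 0.2 + 0.5
  for (off in c("fba", "asm", "lalga", "tpff")) {
    ab <- list(fba = TRUE, asm = TRUE, lalga = TRUE, tpff = TRUE)
    ab[[off]] <- FALSE
    model <- ltpnet(ltpnet_config("tiny", ablation = ab), seed = 4)
    p <- ag_no_grad(tv(ltpnet_forward(model, x)))
    expect_equal(dim(p), c(1L, 1L, 64L, 64L), label = paste("ablation", off))
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(unname(ltpnet_counts(model))[1], 5L)   # dataflow shape unchanged
  }
  # TPFF path-set ablations (structural rows of the path table)
  for (paths in list(c(cp = TRUE, sp = FALSE, dp = FALSE),
                     c(cp = TRUE, sp = TRUE, dp = FALSE),
                     c(cp = TRUE, sp = TRUE, dp = TRUE))) {
    model <- ltpnet(ltpnet_config("tiny", tpff_paths = paths), seed = 4)
    p <- ag_no_grad(tv(ltpnet_forward(model, x)))
    expect_true(all(is.finite(p)))
  }
})

test_that("every parameter receives gradient on a 128x128 batch", {
  model <- tiny_model(seed = 3)   # 128 input: the deepest scan has T = 4 > 1
  set.seed(103)
  x <- array(rnorm(2 * 3 * 128 * 128, 0.5, 0.3), c(2, 3, 128, 128))
  y <- array(rbinom(2 * 128 * 128, 1, 0.3), c(2, 1, 128, 128))
  ltpnet:::module_zero_grad(model)
  loss <- ag_record({
    p <- ltpnet_forward(model, x)
    ltpnet:::t_hybrid_loss(p, y)
  })
  ag_backward(loss)
  ltpnet:::tape_reset()
  ps <- module_parameters(model)
  dead <- names(ps)[vapply(ps, function(p) is.null(p$g) || all(p$g == 0), logical(1))]
  expect_identical(dead, character(0))
})

test_that("checkpoints round-trip weights, config and normalization stats", {
  model <- tiny_model(seed = 9)
  model$norm <- list(mean = c(0.5, 0.4, 0.3), sd = c(0.2, 0.2, 0.2))
  f <- tempfile(fileext = ".rds")
  save_checkpoint(model, f)
  back <- load_checkpoint(f)
  x <- rand_feat(1, 3, 64, 64, seed = 10)
  expect_identical(ag_no_grad(tv(ltpnet_forward(back, x))),
                   ag_no_grad(tv(ltpnet_forward(model, x))))
  expect_equal(back$norm, model$norm)
  unlink(f)
})
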