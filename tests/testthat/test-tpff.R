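# TPFF: simplex-constrained coefficients, the three fusion pathways with
# their residual conventions, path ablation renormalization, and linearity
# in the coefficients.

test_that("normalize_coefficients: defaults, symmetry, simplex, errors", {
  co <- normalize_coefficients()
  expect_equal(c(co$alpha, co$beta, co$gamma), c(0.4, 0.2, 0.4), tolerance = 1e-12)
  eq <- normalize_coefficients(c(1.7, 1.7, 1.7))
  expect_equal(c(eq$alpha, eq$beta, eq$gamma), rep(1 / 3, 3), tolerance = 1e-12)
  set.seed(1)
  for (i in 1:20) {
    co <- normalize_coefficients(rnorm(3, 0, 3))
    expect_lt(abs(co$alpha + co$beta + co$gamma - 1), 1e-12)
    expect_true(all(c(co$alpha, co$beta, co$gamma) > 0))
  }
  expect_error(normalize_coefficients(c(1, NA, 0)), "numeric error")
})

test_that("tpff module initializes at (0.4, 0.2, 0.4)", {
  set.seed(2)
  mod <- new_tpff(8L)
  co <- tpff_coefficients(mod)
  expect_equal(unname(co), c(0.4, 0.2, 0.4), tolerance = 1e-12)
  expect_lt(abs(sum(co) - 1), 1e-12)
})

test_that("common path: zero collapse, symmetry, composition oracle", {
  set.seed(3)
  mod <- new_tpff(8L)
  a <- rand_feat(1, 8, 4, 4, seed = 4)
  # flow = -fhigh with zero-bias CA -> fcp = 0 -> output 0
  expect_equal(max(abs(tv(common_path(mod, a, -a)))), 0)
  b <- rand_feat(1, 8, 4, 4, seed = 5)
  expect_equal(tv(common_path(mod, a, b)), tv(common_path(mod, b, a)))
  fcp <- a + b
  want <- tv(channel_attention_se(mod$children$ca_cp, fcp)) + fcp
  expect_lt(max(abs(tv(common_path(mod, a, b)) - want)), 1e-6)
  expect_error(common_path(mod, a, rand_feat(1, 8, 3, 3)), "shape error")
})

test_that("saliency path residual uses the LOW input", {
  set.seed(6)
  mod <- new_tpff(8L)
  a <- rand_feat(1, 8, 4, 4, seed = 7)
  # fhigh = 0, zero-bias CA -> output = flow exactly
  expect_equal(max(abs(tv(saliency_path(mod, a, array(0, dim(a)))) - a)), 0)
  # fhigh = 1 with CA frozen to unit gates -> 2 * flow
  mod$children$ca_sp$forward <- function(z) ltpnet:::as_tn(z)
  expect_lt(max(abs(tv(saliency_path(mod, a, array(1, dim(a)))) - 2 * a)), 1e-12)
  mod2 <- new_tpff(8L)
  b <- rand_feat(1, 8, 4, 4, seed = 8)
  want <- tv(channel_attention_se(mod2$children$ca_sp, a * b)) + a
  expect_lt(max(abs(tv(saliency_path(mod2, a, b)) - want)), 1e-6)
})

test_that("difference path: zero collapse, core antisymmetry, oracle", {
  set.seed(9)
  mod <- new_tpff(8L)
  a <- rand_feat(1, 8, 4, 4, seed = 10)
  expect_equal(max(abs(tv(difference_path(mod, a, a)) - a)), 0)
  b <- rand_feat(1, 8, 4, 4, seed = 11)
  expect_equal(a - b, -(b - a))                       # fdp antisymmetry
  want <- tv(channel_attention_se(mod$children$ca_dp, a - b)) + a
  expect_lt(max(abs(tv(difference_path(mod, a, b)) - want)), 1e-6)
})

test_that("tpff_forward: masking, shape, linear-combination oracle, linearity", {
  set.seed(12)
  cp_only <- new_tpff(8L, enabled_paths = c(cp = TRUE, sp = FALSE, dp = FALSE))
  hi <- rand_feat(1, 8, 4, 4, seed = 13)
  lo <- rand_feat(1, 8, 4, 4, seed = 14)
  expect_equal(unname(tpff_coefficients(cp_only)), c(1, 0, 0))
  flow <- tv(bgr(cp_only$children$proj_low, lo))
  fhigh <- tv(bgr(cp_only$children$proj_high, hi))
  expect_lt(max(abs(tv(tpff_forward(cp_only, hi, lo)) -
                    tv(common_path(cp_only, flow, fhigh)))), 1e-6)

  mod <- new_tpff(64L)
  hi2 <- rand_feat(1, 64, 16, 16, seed = 15)
  lo2 <- rand_feat(1, 64, 16, 16, seed = 16)
  expect_equal(dim(tv(tpff_forward(mod, hi2, lo2))), c(1L, 64L, 16L, 16L))

  mod8 <- new_tpff(8L)
  fl <- tv(bgr(mod8$children$proj_low, lo))
  fh <- tv(bgr(mod8$children$proj_high, hi))
  p1 <- tv(common_path(mod8, fl, fh))
  p2 <- tv(saliency_path(mod8, fl, fh))
  p3 <- tv(difference_path(mod8, fl, fh))
  co <- tpff_coefficients(mod8)
  expect_lt(max(abs(tv(tpff_forward(mod8, hi, lo)) -
                    (co[1] * p1 + co[2] * p2 + co[3] * p3))), 1e-6)
  # linearity in the coefficients given fixed path outputs (superposition)
  for (tr in 1:3) {
    c1 <- normalize_coefficients(rnorm(3)); c2 <- normalize_coefficients(rnorm(3))
    lam <- runif(1)
    mix <- lam * unlist(c1) + (1 - lam) * unlist(c2)
    out1 <- c1$alpha * p1 + c1$beta * p2 + c1$gamma * p3
    out2 <- c2$alpha * p1 + c2$beta * p2 + c2$gamma * p3
    outm <- mix[1] * p1 + mix[2] * p2 + mix[3] * p3
    expect_lt(max(abs(outm - (lam * out1 + (1 - lam) * out2))), 1e-10)
  }
})

test_that("path ablation renormalizes coefficient mass over active paths", {
  set.seed(17)
  for (en in list(c(cp = TRUE, sp = TRUE, dp = FALSE),
                  c(cp = TRUE, sp = FALSE, dp = TRUE))) {
    mod <- new_tpff(8L, enabled_paths = en)
    co <- tpff_coefficients(mod)
    expect_equal(unname(co[!en]), rep(0, sum(!en)))
    expect_lt(abs(sum(co) - 1), 1e-12)
    out <- tv(tpff_forward(mod, rand_feat(1, 8, 3, 3, seed = 18),
                           rand_feat(1, 8, 3, 3, seed = 19)))
    expect_true(all(is.finite(out)))
  }
  expect_error(new_tpff(8L, enabled_paths = c(cp = FALSE, sp = FALSE, dp = FALSE)),
               "at least one")
})
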