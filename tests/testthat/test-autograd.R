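# The autodiff engine: every primitive's backward pass is validated against
# central finite differences, and the dense convolution / group norm kernels
# additionally against independent direct-loop forward oracles.

grad_of <- function(build, x) {
  xt <- tn_tensor(x, requires_grad = TRUE)
  loss <- ag_record(ltpnet:::t_mean_all(ltpnet:::t_mul(build(xt), build(xt))))
  ag_backward(loss)
  ltpnet:::tape_reset()
  xt$g
}

numeric_loss <- function(build, x) {
  o <- ag_no_grad(tv(build(tn_tensor(x))))
  mean(o * o)
}

test_that("elementwise/pooling/upsampling primitives match finite differences", {
  x <- rand_feat(2, 6, 4, 4, seed = 11)
  cases <- list(
    relu = function(z) ltpnet:::t_relu(z),
    sigmoid = function(z) ltpnet:::t_sigmoid(z),
    gelu = function(z) ltpnet:::t_gelu(z),
    softplus = function(z) ltpnet:::t_softplus(z),
    gap_gate = function(z) ltpnet:::t_mul(z, ltpnet:::t_sigmoid(ltpnet:::t_gap(z))),
    maxmean = function(z) ltpnet:::t_chan_maxmean(z),
    upsample = function(z) ltpnet:::t_upsample_bilinear(z, 2L),
    add_bcast = function(z) ltpnet:::t_add(z, ltpnet:::t_gap(z)),
    sub_mul = function(z) ltpnet:::t_mul(ltpnet:::t_sub(z, 0.3), z)
  )
  for (nm in names(cases)) {
    g <- grad_of(cases[[nm]], x)
    ng <- num_grad(function(v) numeric_loss(cases[[nm]], v), x)
    expect_lt(max(abs(g - ng)), 1e-6, label = paste("grad", nm))
  }
})

test_that("conv2d matches a direct-loop oracle and finite differences", {
  set.seed(5)
  for (k in c(1L, 3L, 7L)) {
    for (stride in if (k == 3L) c(1L, 2L) else 1L) {
      w <- array(rnorm(3 * k * k * 4, 0, 0.3), c(3, k, k, 4))
      b <- rnorm(4, 0, 0.1)
      x <- rand_feat(2, 3, 6, 6, seed = k + stride)
      got <- ag_no_grad(tv(ltpnet:::t_conv2d(x, tn_tensor(w), tn_tensor(b), stride = stride)))
      want <- naive_conv2d(x, w, b, stride = stride)
      expect_equal(got, want, tolerance = 1e-12,
                   label = sprintf("conv k=%d stride=%d", k, stride))
    }
  }
  # gradients wrt input, weight and bias
  w <- tn_tensor(array(rnorm(3 * 9 * 4, 0, 0.3), c(3, 3, 3, 4)), requires_grad = TRUE)
  b <- tn_tensor(rnorm(4, 0, 0.1), requires_grad = TRUE)
  x <- rand_feat(2, 3, 5, 5, seed = 2)
  xt <- tn_tensor(x, requires_grad = TRUE)
  loss <- ag_record({
    o <- ltpnet:::t_conv2d(xt, w, b)
    ltpnet:::t_mean_all(ltpnet:::t_mul(o, o))
  })
  ag_backward(loss); ltpnet:::tape_reset()
  f_at <- function(xv, wv, bv) {
    o <- ag_no_grad(tv(ltpnet:::t_conv2d(xv, tn_tensor(wv), tn_tensor(bv))))
    mean(o * o)
  }
  expect_lt(max(abs(xt$g - num_grad(function(v) f_at(v, w$v, b$v), x))), 1e-6)
  expect_lt(max(abs(w$g - num_grad(function(v) f_at(x, array(v, dim(w$v)), b$v), w$v))), 1e-6)
  expect_lt(max(abs(b$g - num_grad(function(v) f_at(x, w$v, v), b$v))), 1e-6)
})

test_that("group/batch norm match oracles and finite differences", {
  x <- rand_feat(2, 6, 3, 3, seed = 9)
  gam <- runif(6, 0.5, 1.5); bet <- rnorm(6, 0, 0.2)
  got <- ag_no_grad(tv(ltpnet:::t_groupnorm(x, tn_tensor(gam), tn_tensor(bet), 3L)))
  expect_equal(got, naive_groupnorm(x, gam, bet, 3L), tolerance = 1e-10)

  gt <- tn_tensor(gam, requires_grad = TRUE)
  bt <- tn_tensor(bet, requires_grad = TRUE)
  xt <- tn_tensor(x, requires_grad = TRUE)
  loss <- ag_record({
    o <- ltpnet:::t_groupnorm(xt, gt, bt, 3L)
    ltpnet:::t_mean_all(ltpnet:::t_mul(o, o))
  })
  ag_backward(loss); ltpnet:::tape_reset()
  f_at <- function(xv, gv, bv) {
    o <- ag_no_grad(tv(ltpnet:::t_groupnorm(xv, tn_tensor(gv), tn_tensor(bv), 3L)))
    mean(o * o)
  }
  expect_lt(max(abs(xt$g - num_grad(function(v) f_at(v, gam, bet), x))), 1e-5)
  expect_lt(max(abs(gt$g - num_grad(function(v) f_at(x, v, bet), gam))), 1e-5)
  expect_lt(max(abs(bt$g - num_grad(function(v) f_at(x, gam, v), bet))), 1e-5)

  st <- new.env(); st$running_mean <- rep(0, 6); st$running_var <- rep(1, 6)
  g2 <- grad_of(function(z) ltpnet:::t_batchnorm(z, tn_tensor(gam), tn_tensor(bet), st, TRUE), x)
  n2 <- num_grad(function(v) {
    o <- ag_no_grad(tv(ltpnet:::t_batchnorm(v, tn_tensor(gam), tn_tensor(bet), st, TRUE)))
    mean(o * o)
  }, x)
  expect_lt(max(abs(g2 - n2)), 1e-5)
})

test_that("selective-scan primitive gradients match finite differences", {
  set.seed(3)
  mod <- ltpnet:::new_ss2d(3L, 2L)
  x <- rand_feat(2, 3, 3, 2, seed = 4)
  for (nm in names(mod$params)) {
    p <- mod$params[[nm]]
    for (q in mod$params) q$g <- NULL
    loss <- ag_record({
      o <- mod$forward(tn_tensor(x))
      ltpnet:::t_mean_all(ltpnet:::t_mul(o, o))
    })
    ag_backward(loss); ltpnet:::tape_reset()
    ng <- num_grad(function(v) {
      old <- p$v; p$v <- array(v, dim(p$v))
      o <- ag_no_grad(tv(mod$forward(tn_tensor(x))))
      p$v <- old
      mean(o * o)
    }, p$v)
    expect_lt(max(abs(p$g - ng)), 1e-6, label = paste("ss2d grad", nm))
  }
  g <- grad_of(function(z) mod$forward(z), x)
  ng <- num_grad(function(v) numeric_loss(function(z) mod$forward(z), v), x)
  expect_lt(max(abs(g - ng)), 1e-6)
})

test_that("gradients accumulate across reuse and ag_no_grad detaches", {
  x <- tn_tensor(rand_feat(1, 2, 2, 2, seed = 6), requires_grad = TRUE)
  loss <- ag_record({
    y <- ltpnet:::t_add(x, x)                     # reuse of the same leaf
    ltpnet:::t_mean_all(y)
  })
  ag_backward(loss); ltpnet:::tape_reset()
  expect_equal(max(abs(x$g - 2 / length(x$v))), 0)
  x$g <- NULL
  out <- ag_no_grad(ltpnet:::t_add(x, 1))
  expect_false(out$rq)
})
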