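# ASM: selective scan versus a brute-force per-timestep oracle, unfold/fold
# round trips, RGA composition and residual collapse, and the DB/FFN
# sandwich + upsample contract.

test_that("ss2d matches the brute-force recurrence oracle", {
  set.seed(1)
  mod <- ltpnet:::new_ss2d(8L, 8L)
  for (i in 1:3) {
    x <- rand_feat(1, 8, 4, 4, seed = 10 + i)
    expect_lt(max(abs(tv(ss2d(mod, x)) - naive_ss2d(x, mod))), 1e-5)
  }
  # non-square map, batch > 1
  mod2 <- ltpnet:::new_ss2d(4L, 3L)
  x <- rand_feat(2, 4, 3, 5, seed = 20)
  expect_lt(max(abs(tv(ss2d(mod2, x)) - naive_ss2d(x, mod2))), 1e-5)
})

test_that("ss2d degenerate parameters give 4*f; unfold/fold is a bijection", {
  set.seed(2)
  mod <- ltpnet:::new_ss2d(4L, 4L)
  mod$params$WC$v[] <- 0
  mod$params$D$v[] <- 1
  x <- rand_feat(2, 4, 3, 3, seed = 3)
  expect_lt(max(abs(tv(ss2d(mod, x)) - 4 * x)), 1e-12)

  seqs <- ltpnet:::ss2d_unfold(x)
  for (d in names(seqs)) {
    expect_identical(ltpnet:::ss2d_fold(seqs[[d]], d, 3L, 3L), x)
  }
})

test_that("rga: residual collapse, shape, composition oracle", {
  set.seed(4)
  mod <- new_rga(16L)
  x <- rand_feat(2, 16, 8, 8, seed = 5)
  expect_equal(dim(tv(rga(mod, x))), c(2L, 16L, 8L, 8L))

  got <- tv(rga(mod, x))
  a <- cgr(mod$children$branch_a, x)
  b <- cgr(mod$children$branch_b, x)
  want <- tv(cgr(mod$children$refine, tv(a) * tv(b))) + x
  expect_lt(max(abs(got - want)), 1e-6)

  zero_params(mod)
  expect_equal(max(abs(tv(rga(mod, x)) - x)), 0)    # CGR(0)=0 residual identity
})

test_that("rga_ss2d is the elementwise sum of its branches", {
  set.seed(6)
  mod <- new_rga_ss2d(8L, state_dim = 4L)
  x <- rand_feat(1, 8, 4, 4, seed = 7)
  got <- tv(rga_ss2d(mod, x))
  want <- tv(ss2d(mod$children$ss2d, x)) + tv(rga(mod$children$rga, x))
  expect_lt(max(abs(got - want)), 1e-6)

  # rga frozen to identity, ss2d to 4*f -> 5*f
  zero_params(mod$children$rga)
  mod$children$ss2d$params$Wd$v[] <- 0; mod$children$ss2d$params$bd$v[] <- 0
  mod$children$ss2d$params$WB$v[] <- 0; mod$children$ss2d$params$WC$v[] <- 0
  mod$children$ss2d$params$D$v[] <- 1
  expect_lt(max(abs(tv(rga_ss2d(mod, x)) - 5 * x)), 1e-12)

  # both branches frozen to emit zeros
  mod$children$ss2d$params$D$v[] <- 0
  mod2 <- mod
  # rga zeroed leaves its +f residual; subtract to isolate the frozen sum
  expect_lt(max(abs(tv(rga_ss2d(mod2, x)) - x)), 1e-12)
})

test_that("asm_forward doubles spatial extents, projects channels, composes", {
  set.seed(8)
  mod <- new_asm(128L, 96L, state_dim = 4L)
  out <- tv(asm_forward(mod, rand_feat(1, 128, 4, 4, seed = 9)))
  expect_equal(dim(out), c(1L, 96L, 8L, 8L))

  small <- new_asm(8L, 8L, state_dim = 4L)
  x <- rand_feat(2, 8, 3, 3, seed = 10)
  ch <- small$children
  f1 <- ltpnet:::t_add(ch$ffn1$forward(ch$db1$forward(ltpnet:::as_tn(x))), x)
  f2 <- ltpnet:::t_add(ch$core$forward(f1), f1)
  f3 <- ltpnet:::t_add(ch$ffn2$forward(ch$db2$forward(f2)), f2)
  want <- tv(ch$proj$forward(ltpnet:::t_upsample_bilinear(f3, 2L)))
  expect_lt(max(abs(tv(asm_forward(small, x)) - want)), 1e-5)

  for (hw in list(c(1L, 1L), c(2L, 5L), c(4L, 4L))) {
    o <- tv(asm_forward(small, rand_feat(1, 8, hw[1], hw[2], seed = sum(hw))))
    expect_equal(dim(o)[3:4], 2L * hw)
  }
})

test_that("asm residual sandwich collapses when DB/FFN parameters are zeroed", {
  set.seed(11)
  mod <- new_asm(8L, 8L, state_dim = 4L)
  zero_params(mod$children$db1); zero_params(mod$children$ffn1)
  zero_params(mod$children$db2); zero_params(mod$children$ffn2)
  x <- rand_feat(1, 8, 3, 3, seed = 12)
  ch <- mod$children
  # f1 = FFN(DB(x)) + x = x ;  f3 = FFN(DB(f2)) + f2 = f2
  f1 <- tv(ltpnet:::t_add(ch$ffn1$forward(ch$db1$forward(ltpnet:::as_tn(x))), x))
  expect_equal(max(abs(f1 - x)), 0)
  # additionally zeroing the core makes f2 = RGA-SS2D(f1) + f1 = 2*f1
  zero_params(ch$core)
  f2 <- tv(ltpnet:::t_add(ch$core$forward(ltpnet:::as_tn(f1)), f1))
  expect_lt(max(abs(f2 - 2 * x)), 1e-12)
  want <- tv(ch$proj$forward(ltpnet:::t_upsample_bilinear(ltpnet:::as_tn(f2), 2L)))
  expect_lt(max(abs(tv(asm_forward(mod, x)) - want)), 1e-12)
})
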