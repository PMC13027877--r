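# PNG codec, pair loading/resizing, augmentation, the cosine schedule, and
# the evaluation contract (tie rule, oracle predictor, metric identity).

test_that("PNG codec round-trips gray and RGB and validates CRC-32", {
  set.seed(1)
  img <- array(runif(20 * 14 * 3), c(20, 14, 3))
  f <- tempfile(fileext = ".png")
  write_png(img, f)
  back <- read_png(f)
  expect_equal(back, round(img * 255) / 255, tolerance = 1e-12)
  m <- matrix(rbinom(20 * 14, 1, 0.4), 20, 14)
  write_png(m, f)
  expect_identical(read_png(f), m / 1)
  # CRC-32 known test vector
  expect_equal(ltpnet:::crc32(charToRaw("123456789")), 3421780262)
  expect_error(read_png(tempfile()), "missing file")
  unlink(f)
})

test_that("load_pair resizes image bilinearly and keeps the mask binary", {
  d <- tempfile("pairs")
  g <- generate_lesion_image(synth_params(image_size = c(96L, 96L), seed = 2L))
  dir.create(d)
  ip <- file.path(d, "img.png"); mp <- file.path(d, "mask.png")
  write_png(g$image, ip); write_png(g$mask + 0, mp)

  pr <- load_pair(ip, mp, size = c(64L, 64L))
  expect_equal(dim(pr$image), c(64L, 64L, 3L))
  expect_true(all(pr$mask %in% c(0L, 1L)))

  native <- load_pair(ip, mp)                 # identity resize
  expect_identical(native$mask, g$mask)
  expect_equal(native$image, round(g$image * 255) / 255, tolerance = 1e-12)
  nat2 <- load_pair(ip, mp, size = c(96L, 96L))
  expect_identical(nat2$mask, g$mask)

  write_png(matrix(0.37, 8, 8), mp)           # non-binary mask
  expect_error(load_pair(ip, mp), "input error")
  expect_error(load_pair(file.path(d, "none.png"), mp), "missing")
  unlink(d, recursive = TRUE)
})

test_that("augmentation applies one lattice bijection to both image and mask", {
  g <- generate_lesion_image(synth_params(seed = 3L))
  set.seed(10)
  for (i in 1:10) {
    a <- augment_pair(g$image, g$mask)
    expect_equal(sum(a$mask), sum(g$mask))                 # area preserved
    expect_true(all(a$mask %in% c(0L, 1L)))
    expect_equal(sort(as.vector(a$image)), sort(as.vector(g$image)))
  }
  # horizontal flip is an involution
  f1 <- ltpnet:::apply_dihedral(g$image, 0L, TRUE, FALSE)
  expect_identical(ltpnet:::apply_dihedral(f1, 0L, TRUE, FALSE), g$image)
  # fixed seed -> reproducible transform sequence
  set.seed(42); a1 <- augment_pair(g$image, g$mask)
  set.seed(42); a2 <- augment_pair(g$image, g$mask)
  expect_identical(a1, a2)
})

test_that("cosine schedule matches its closed form at 0, T/2 and T", {
  lr0 <- 1e-3; lrm <- 1e-5; T_ <- 300
  expect_equal(cosine_lr(0, T_, lr0, lrm), lr0)
  expect_equal(cosine_lr(T_ / 2, T_, lr0, lrm), (lr0 + lrm) / 2)
  expect_equal(cosine_lr(T_, T_, lr0, lrm), lrm)
  expect_true(all(diff(cosine_lr(0:T_, T_, lr0, lrm)) < 0))
})

test_that("evaluation: oracle predictor scores 1, tie rule, metric identity", {
  pairs <- make_synth_pairs(2, seed0 = 40)
  stub <- function(fn) {
    m <- ltpnet:::new_module("stub")
    m$forward <- fn
    m$norm <- NULL
    m$cfg <- list(threshold = 0.5)
    m
  }
  b <- ltpnet:::pairs_to_batch(pairs)
  oracle <- stub(function(x) ltpnet:::as_tn(b$y * 0.998 + 0.001))
  ev <- evaluate_ltpnet(oracle, pairs)
  expect_equal(unlist(ev$metrics[c("acc", "sen", "spe", "dsc", "miou")]),
               c(acc = 1, sen = 1, spe = 1, dsc = 1, miou = 1))
  expect_equal(ev$metrics$miou, ev$metrics$dsc / (2 - ev$metrics$dsc), tolerance = 1e-9)

  # constant 0.5 predictor under the ">= threshold" tie rule: all positive
  const <- stub(function(x) ltpnet:::as_tn(array(0.5, dim(b$y))))
  ev2 <- evaluate_ltpnet(const, pairs)
  expect_equal(ev2$metrics$sen, 1)
  expect_equal(ev2$metrics$spe, 0)
  expect_error(evaluate_ltpnet(const, pairs, threshold = 0), "configuration error")
})

test_that("load_split round-trips a generated split", {
  d <- tempfile("split")
  generate_split(3L, synth_params(seed = 6L), d)
  pairs <- load_split(d)
  expect_length(pairs, 3L)
  g1 <- generate_lesion_image(synth_params(seed = 6L))
  expect_identical(pairs[[1]]$mask, g1$mask)
  unlink(d, recursive = TRUE)
})
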