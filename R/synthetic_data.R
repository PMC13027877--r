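# Procedural generator of dermoscopy-like image/mask pairs.  Each image is a
# skin-tone background with smooth low-frequency texture containing a single
# star-convex lesion (an ellipse perturbed by random radial harmonics,
# guaranteeing one 4-connected component), darkened in proportion to the
# contrast parameter, alpha-blended with a Gaussian-blurred boundary, and
# optionally occluded by dark hair-like Bezier strokes drawn after lesion
# compositing (excluded from the mask, matching ground-truth semantics of
# dermoscopy datasets).  The mask is the exact pre-blur lesion region.
# Three named regimes emulate the classic challenge cases: complex
# background (hair interference), blurred boundaries, low lesion-skin
# contrast.

#' Synthetic-data parameters
#'
#' @param image_size `(H, W)` in pixels.
#' @param lesion_area_fraction `(min, max)` interval of mask coverage;
#'   enforced by bounded rejection sampling.
#' @param contrast in `[0, 1]`; scales the lesion-skin intensity separation.
#' @param boundary_blur_sigma Gaussian sigma (pixels) of the boundary blend.
#' @param hair_count number of dark hair strokes.
#' @param hair_width stroke width in pixels.
#' @param noise_sigma additive Gaussian pixel noise.
#' @param seed integer seed; identical parameters give bitwise-identical
#'   image/mask pairs.
#' @return a `synth_params` list.
#' @export
synth_params <- function(image_size = c(64L, 64L),
                         lesion_area_fraction = c(0.08, 0.35),
                         contrast = 0.6, boundary_blur_sigma = 1.2,
                         hair_count = 3L, hair_width = 1.5,
                         noise_sigma = 0.02, seed = 1L) {
  f <- lesion_area_fraction
  if (!(f[1] > 0 && f[1] <= f[2] && f[2] < 0.9)) {
    stop("lesion_area_fraction must satisfy 0 < min <= max < 0.9")
  }
  if (contrast < 0 || contrast > 1) stop("contrast must lie in [0, 1]")
  if (any(image_size < 16)) stop("image_size too small")
  structure(list(image_size = as.integer(image_size),
                 lesion_area_fraction = f, contrast = contrast,
                 boundary_blur_sigma = boundary_blur_sigma,
                 hair_count = as.integer(hair_count), hair_width = hair_width,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "synth_params")
}

#' Parameters of a named challenge regime
#'
#' @param regime `"complex"` (hair-cluttered background), `"blurred"`
#'   (diffuse lesion boundary) or `"lowcontrast"` (small lesion-skin
#'   separation).
#' @param ... overrides forwarded to [synth_params()].
#' @return a `synth_params` list.
#' @export
synth_regime <- function(regime = c("complex", "blurred", "lowcontrast"), ...) {
  regime <- match.arg(regime)
  base <- switch(regime,
    complex = list(hair_count = 6L, boundary_blur_sigma = 0.8, contrast = 0.7),
    blurred = list(hair_count = 0L, boundary_blur_sigma = 3.0, contrast = 0.6),
    lowcontrast = list(hair_count = 1L, boundary_blur_sigma = 1.2, contrast = 0.15))
  p <- do.call(synth_params, utils::modifyList(base, list(...)))
  p$regime <- regime
  p
}

# Star-convex lesion mask: boundary radius r(theta) = 1 + sum_k a_k
# cos(k theta + phi_k), k in 2..6, |a_k| <= 0.25, in rotated-ellipse
# coordinates sized to hit the target area fraction.
lesion_mask <- function(H, W, frac) {
  cy <- H / 2 + stats::runif(1, -0.15, 0.15) * H
  cx <- W / 2 + stats::runif(1, -0.15, 0.15) * W
  ak <- stats::runif(5, -1, 1) * 0.25 / (1 + 0.3 * (0:4))
  ph <- stats::runif(5, 0, 2 * pi)
  q <- stats::runif(1, 0.6, 1)              # aspect ratio b/a
  rot <- stats::runif(1, 0, pi)
  area <- frac * H * W
  ab <- area / (pi * (1 + sum(ak^2) / 2))   # product of semi-axes
  a <- sqrt(ab / q); b <- ab / a
  yy <- matrix(seq_len(H), H, W) - cy
  xx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  u <- (cos(rot) * xx + sin(rot) * yy) / a
  v <- (-sin(rot) * xx + cos(rot) * yy) / b
  rr <- sqrt(u^2 + v^2)
  th <- atan2(v, u)
  rb <- 1
  for (k in 2:6) rb <- rb + ak[k - 1] * cos(k * th + ph[k - 1])
  (rr <= rb) * 1L
}

# Smooth low-frequency field in roughly [-1, 1], for skin/lesion texture.
lowfreq_field <- function(H, W, sigma) {
  f <- gaussian_blur(matrix(stats::rnorm(H * W), H, W), sigma)
  s <- stats::sd(f)
  if (s > 0) f / (3 * s) else f
}

draw_hairs <- function(img, n, width) {
  if (n <= 0) return(img)
  H <- dim(img)[1]; W <- dim(img)[2]
  r <- max(0.5, width / 2)
  off <- expand.grid(dy = -ceiling(r):ceiling(r), dx = -ceiling(r):ceiling(r))
  off <- off[off$dy^2 + off$dx^2 <= r^2 + 0.25, , drop = FALSE]
  for (s in seq_len(n)) {
    pts <- cbind(stats::runif(4, -0.2, 1.2) * H, stats::runif(4, -0.2, 1.2) * W)
    t <- seq(0, 1, length.out = 4L * max(H, W))
    bz <- function(col) {
      (1 - t)^3 * pts[1, col] + 3 * (1 - t)^2 * t * pts[2, col] +
        3 * (1 - t) * t^2 * pts[3, col] + t^3 * pts[4, col]
    }
    y <- round(bz(1)); x <- round(bz(2))
    shade <- stats::runif(1, 0.05, 0.2)
    for (o in seq_len(nrow(off))) {
      yy <- y + off$dy[o]; xx <- x + off$dx[o]
      ok <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
      idx <- cbind(yy[ok], xx[ok])
      for (c in 1:3) {
        pl <- img[, , c]
        pl[idx] <- shade * c(1, 0.9, 0.8)[c]
        img[, , c] <- pl
      }
    }
  }
  img
}

#' Generate one dermoscopy-like image/mask pair
#'
#' @param p a [synth_params()] (or [synth_regime()]) list.
#' @return list with `image` (H, W, 3) in `[0, 1]`, `mask` (H, W) integer
#'   0/1, and `area_fraction` actually achieved.
#' @export
generate_lesion_image <- function(p) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
            rm(".Random.seed", envir = globalenv()))
  set.seed(p$seed)
  H <- p$image_size[1]; W <- p$image_size[2]
  fr <- p$lesion_area_fraction

  # skin background: tan tone + per-image jitter + smooth texture
  tone <- c(0.86, 0.67, 0.55) + stats::runif(3, -0.05, 0.05)
  tex <- lowfreq_field(H, W, max(2, H / 10))
  skin <- array(0, c(H, W, 3))
  for (c in 1:3) skin[, , c] <- pmin(pmax(tone[c] + 0.04 * tex, 0), 1)

  # lesion mask with bounded rejection on achieved coverage
  mask <- NULL
  for (try in 1:50) {
    m <- lesion_mask(H, W, stats::runif(1, fr[1], fr[2]))
    cov <- mean(m)
    if (cov >= fr[1] && cov <= fr[2] && sum(m) >= 12) { mask <- m; break }
  }
  if (is.null(mask)) stop("generation error: lesion area fraction unattainable")

  # lesion appearance: darker brown, separation scaled by contrast
  ltex <- lowfreq_field(H, W, max(1.5, H / 16))
  dark <- 0.75 * p$contrast
  lesion <- array(0, c(H, W, 3))
  lcol <- tone * (1 - dark) * c(0.95, 0.8, 0.75)
  for (c in 1:3) lesion[, , c] <- pmin(pmax(lcol[c] + 0.05 * ltex, 0), 1)

  alpha <- gaussian_blur(mask + 0, p$boundary_blur_sigma)
  img <- skin
  for (c in 1:3) img[, , c] <- skin[, , c] * (1 - alpha) + lesion[, , c] * alpha

  img <- draw_hairs(img, p$hair_count, p$hair_width)
  if (p$noise_sigma > 0) img <- img + array(stats::rnorm(H * W * 3, 0, p$noise_sigma), c(H, W, 3))
  img <- pmin(pmax(img, 0), 1)
  list(image = img, mask = matrix(as.integer(mask), H, W), area_fraction = mean(mask))
}

#' Generate a dataset split on disk
#'
#' Writes `n` image/mask PNG pairs in an ISIC-style layout
#' (`images/img_XXXX.png`, `masks/img_XXXX_mask.png`) plus a JSON manifest
#' (filename, mask, seed, regime, area fraction).  Mask PNGs contain only
#' the values 0 and 255.  Regenerating with the manifest seeds reproduces
#' byte-identical files.
#'
#' @param n number of pairs (>= 1).
#' @param p base [synth_params()]; pair `i` uses seed `p$seed + i - 1`.
#' @param out_dir output directory (created if missing).
#' @return the manifest as a data frame, invisibly written to
#'   `manifest.json`.
#' @export
generate_split <- function(n, p, out_dir) {
  stopifnot(n >= 1)
  img_dir <- file.path(out_dir, "images")
  msk_dir <- file.path(out_dir, "masks")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(msk_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(img_dir)) stop("I/O error: cannot create ", img_dir)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    pi <- p
    pi$seed <- p$seed + i - 1L
    g <- generate_lesion_image(pi)
    fn <- sprintf("img_%04d.png", i)
    mn <- sprintf("img_%04d_mask.png", i)
    write_png(g$image, file.path(img_dir, fn))
    write_png(g$mask + 0, file.path(msk_dir, mn))
    rows[[i]] <- data.frame(file = file.path("images", fn),
                            mask = file.path("masks", mn),
                            seed = pi$seed,
                            regime = if (is.null(p$regime)) "default" else p$regime,
                            area_fraction = g$area_fraction,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
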