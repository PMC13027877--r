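# Dataset reading, resizing and augmentation.  Images are resized with
# bilinear interpolation and kept in [0, 1]; masks with nearest-neighbor
# interpolation so the label set {0, 1} is preserved exactly.  Augmentation
# applies the SAME spatial transform to image and mask: horizontal/vertical
# flips and right-angle rotations (which are lattice bijections, so the mask
# positive-pixel count is preserved exactly).

#' Load an image/mask pair
#'
#' @param image_path path to an RGB PNG.
#' @param mask_path path to a single-channel binary mask PNG (values 0/255).
#' @param size optional `(H, W)`: image resized bilinearly, mask with
#'   nearest-neighbor.
#' @return list with `image` (H, W, 3) in `[0, 1]` and `mask` (H, W)
#'   integer 0/1.
#' @export
load_pair <- function(image_path, mask_path, size = NULL) {
  if (!file.exists(image_path)) stop("I/O error: missing file ", image_path)
  if (!file.exists(mask_path)) stop("I/O error: missing file ", mask_path)
  img <- read_png(image_path)
  if (length(dim(img)) == 2L) {
    img <- array(rep(img, 3L), c(dim(img), 3L))
  }
  msk <- read_png(mask_path)
  if (length(dim(msk)) == 3L) msk <- msk[, , 1]
  if (any(pmin(abs(msk), abs(msk - 1)) > 0.02)) {
    stop("input error: mask contains values other than 0 and 255")
  }
  msk <- (msk > 0.5) * 1L
  if (!is.null(size)) {
    img <- pmin(pmax(resize_bilinear(img, size[1], size[2]), 0), 1)
    msk <- resize_nearest(msk, size[1], size[2])
  }
  list(image = img, mask = matrix(as.integer(msk), nrow(msk), ncol(msk)))
}

#' Load every pair listed in a split's manifest
#' @param data_dir directory written by [generate_split()] (or any directory
#'   with a compatible `manifest.json`).
#' @param size optional `(H, W)` resize.
#' @return list of pairs as returned by [load_pair()].
#' @export
load_split <- function(data_dir, size = NULL) {
  mf <- file.path(data_dir, "manifest.json")
  if (!file.exists(mf)) stop("I/O error: no manifest.json in ", data_dir)
  manifest <- jsonlite::fromJSON(mf)
  lapply(seq_len(nrow(manifest)), function(i) {
    load_pair(file.path(data_dir, manifest$file[i]),
              file.path(data_dir, manifest$mask[i]), size = size)
  })
}

rot90ccw <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]

apply_dihedral <- function(x, k, fh, fv) {   # x: (H,W) or (H,W,C)
  one <- function(m) {
    if (fh) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
    if (fv) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
    if (k > 0) for (j in seq_len(k)) m <- rot90ccw(m)
    m
  }
  d <- dim(x)
  if (length(d) == 2L) return(one(x))
  out <- NULL
  for (c in seq_len(d[3])) {
    m <- one(x[, , c])
    if (is.null(out)) out <- array(0, c(dim(m), d[3]))
    out[, , c] <- m
  }
  out
}

#' Randomly augment an aligned image/mask pair
#'
#' Draws a horizontal flip, a vertical flip and a rotation from
#' `{0, 90, 180, 270}` degrees, and applies the same transform to both.
#'
#' @param image (H, W, 3) array.
#' @param mask (H, W) binary matrix.
#' @return list with transformed `image` and `mask`.
#' @export
augment_pair <- function(image, mask) {
  fh <- stats::runif(1) < 0.5
  fv <- stats::runif(1) < 0.5
  k <- sample(0:3, 1)
  list(image = apply_dihedral(image, k, fh, fv),
       mask = apply_dihedral(mask, k, fh, fv))
}

# Stack a list of pairs into model-layout arrays: (B,3,H,W) and (B,1,H,W).
pairs_to_batch <- function(pairs) {
  B <- length(pairs)
  d <- dim(pairs[[1]]$image)
  x <- array(0, c(B, 3L, d[1], d[2]))
  y <- array(0, c(B, 1L, d[1], d[2]))
  for (i in seq_len(B)) {
    x[i, , , ] <- aperm(pairs[[i]]$image, c(3, 1, 2))
    y[i, 1L, , ] <- pairs[[i]]$mask
  }
  list(x = x, y = y)
}
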