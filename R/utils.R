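# Small image utilities shared by the data pipeline and the synthetic
# generator: separable resizing, Gaussian blur, connected-component labeling.

#' Bilinear resize of an image array
#' @param img numeric (H, W) or (H, W, C) array.
#' @param out_h,out_w target extents.
#' @return resized array.
#' @export
resize_bilinear <- function(img, out_h, out_w) {
  d <- dim(img)
  Uh <- bilinear_matrix(out_h, d[1])
  Uw <- bilinear_matrix(out_w, d[2])
  if (length(d) == 2L) {
    Uh %*% img %*% t(Uw)
  } else {
    out <- array(0, c(out_h, out_w, d[3]))
    for (c in seq_len(d[3])) out[, , c] <- Uh %*% img[, , c] %*% t(Uw)
    out
  }
}

# Center-rule nearest-neighbor index map.
nearest_index <- function(out_n, in_n) {
  pmin(pmax(floor(((seq_len(out_n) - 0.5) * in_n) / out_n) + 1, 1), in_n)
}

#' Nearest-neighbor resize (label-set preserving; used for masks)
#' @inheritParams resize_bilinear
#' @export
resize_nearest <- function(img, out_h, out_w) {
  d <- dim(img)
  iy <- nearest_index(out_h, d[1])
  ix <- nearest_index(out_w, d[2])
  if (length(d) == 2L) img[iy, ix] else img[iy, ix, , drop = FALSE]
}

# Separable Gaussian blur with reflected borders, kernel radius 3*sigma.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  blur1 <- function(m) {   # along rows (dim 1)
    n <- nrow(m)
    idx <- function(i) pmin(pmax(i, 1L), n)   # replicate borders
    out <- 0
    for (j in -r:r) out <- out + k[j + r + 1] * m[idx(seq_len(n) + j), , drop = FALSE]
    out
  }
  d <- dim(img)
  one <- function(m) t(blur1(t(blur1(m))))
  if (length(d) == 2L) one(img) else {
    out <- img
    for (c in seq_len(d[3])) out[, , c] <- one(img[, , c])
    out
  }
}

#' Label 4-connected components of a binary mask
#' @param mask logical or 0/1 matrix.
#' @return integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask) {
  m <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  H <- nrow(m); W <- ncol(m)
  labels <- matrix(0L, H, W)
  lab <- 0L
  todo <- which(m & labels == 0L)
  while (length(todo) > 0) {
    seed <- todo[1]
    lab <- lab + 1L
    frontier <- seed
    labels[seed] <- lab
    while (length(frontier) > 0) {
      i <- frontier
      h <- ((i - 1L) %% H) + 1L
      nb <- c(i[h > 1L] - 1L, i[h < H] + 1L, i[i > H] - H, i[i <= H * (W - 1L)] + H)
      nb <- unique(nb[m[nb] & labels[nb] == 0L])
      labels[nb] <- lab
      frontier <- nb
    }
    todo <- which(m & labels == 0L)
  }
  labels
}
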