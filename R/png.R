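# Minimal PNG codec (8-bit grayscale and RGB, no interlace).  The base R
# toolchain in this package's target environment has no PNG reader, but
# memCompress()/memDecompress() with type "gzip" operate on zlib (RFC 1950)
# streams -- exactly the format of PNG IDAT chunks -- so only chunk framing,
# CRC-32 and scanline (un)filtering are implemented here.  Files are written
# with filter type 0; all five filter types are supported on read.

.png_env <- new.env(parent = emptyenv())

xor32 <- function(a, b) {   # bitwise xor of two doubles in [0, 2^32)
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  as.numeric(hi) * 65536 + as.numeric(lo)
}

crc32_table <- function() {
  if (!is.null(.png_env$crc_tab)) return(.png_env$crc_tab)
  tab <- numeric(256)
  for (i in 0:255) {
    t <- as.numeric(i)
    for (k in 1:8) {
      t <- if (t %% 2 == 1) xor32(floor(t / 2), 3988292384) else floor(t / 2)
    }
    tab[i + 1] <- t
  }
  .png_env$crc_tab <- tab
  tab
}

crc32 <- function(bytes) {
  tab <- crc32_table()
  crc <- 4294967295
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    idx <- bitwXor(as.integer(crc %% 256), b[i])
    crc <- xor32(floor(crc / 256), tab[idx + 1])
  }
  xor32(crc, 4294967295)
}

u32_bytes <- function(x) {
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256, x %% 256))
}

bytes_u32 <- function(r) sum(as.numeric(as.integer(r)) * c(16777216, 65536, 256, 1))

png_chunk <- function(type, data) {
  td <- c(charToRaw(type), data)
  c(u32_bytes(length(data)), td, u32_bytes(crc32(td)))
}

#' Write an 8-bit PNG file
#'
#' @param img numeric array in `[0, 1]`: (H, W) grayscale or (H, W, 3) RGB.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_png <- function(img, path) {
  d <- dim(img)
  if (is.null(d) || !(length(d) %in% c(2L, 3L))) stop("img must be (H,W) or (H,W,3)")
  nc <- if (length(d) == 2L) 1L else d[3]
  if (!nc %in% c(1L, 3L)) stop("only grayscale and RGB are supported")
  H <- d[1]; W <- d[2]
  v <- pmin(pmax(img, 0), 1)
  bytes <- as.integer(round(v * 255))
  # interleave channels per pixel, rows top-to-bottom
  if (nc == 1L) {
    px <- t(matrix(bytes, H, W))                     # (W,H): column o fastest
    sl <- matrix(as.raw(px), W, H)
  } else {
    a <- aperm(array(bytes, c(H, W, 3L)), c(3, 2, 1)) # (C,W,H)
    sl <- matrix(as.raw(a), 3L * W, H)
  }
  raw_data <- as.raw(rbind(matrix(as.raw(0L), 1, H), sl))  # filter byte 0 per row
  ihdr <- c(u32_bytes(W), u32_bytes(H), as.raw(c(8L, if (nc == 1L) 0L else 2L, 0L, 0L, 0L)))
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", memCompress(raw_data, type = "gzip")),
           png_chunk("IEND", raw()))
  writeBin(out, path)
  invisible(path)
}

paeth <- function(a, b, c) {
  p <- a + b - c
  pa <- abs(p - a); pb <- abs(p - b); pc <- abs(p - c)
  ifelse(pa <= pb & pa <= pc, a, ifelse(pb <= pc, b, c))
}

#' Read an 8-bit PNG file
#'
#' Supports bit depth 8, color types 0 (grayscale) and 2 (RGB),
#' non-interlaced.
#'
#' @param path file path.
#' @return numeric array in `[0, 1]`: (H, W) or (H, W, 3).
#' @export
read_png <- function(path) {
  if (!file.exists(path)) stop("I/O error: missing file ", path)
  r <- readBin(path, "raw", file.info(path)$size)
  if (length(r) < 8 || !identical(as.integer(r[1:8]), c(137L, 80L, 78L, 71L, 13L, 10L, 26L, 10L))) {
    stop("I/O error: not a PNG file: ", path)
  }
  pos <- 9L
  W <- H <- nc <- NULL
  idat <- raw()
  while (pos + 7L <= length(r)) {
    len <- bytes_u32(r[pos:(pos + 3L)])
    type <- rawToChar(r[(pos + 4L):(pos + 7L)])
    data <- if (len > 0) r[(pos + 8L):(pos + 7L + len)] else raw()
    if (type == "IHDR") {
      W <- bytes_u32(data[1:4]); H <- bytes_u32(data[5:8])
      depth <- as.integer(data[9]); ct <- as.integer(data[10])
      if (depth != 8L || !(ct %in% c(0L, 2L)) || as.integer(data[13]) != 0L) {
        stop("input error: only 8-bit non-interlaced grayscale/RGB PNGs are supported")
      }
      nc <- if (ct == 0L) 1L else 3L
    } else if (type == "IDAT") {
      idat <- c(idat, data)
    } else if (type == "IEND") break
    pos <- pos + 12L + len
  }
  if (is.null(W)) stop("I/O error: corrupt PNG (no IHDR)")
  dec <- as.integer(memDecompress(idat, type = "gzip"))
  bpr <- nc * W + 1L
  if (length(dec) != bpr * H) stop("I/O error: corrupt PNG (bad IDAT length)")
  img <- matrix(0L, nc * W, H)
  prev <- integer(nc * W)
  for (row in seq_len(H)) {
    off <- (row - 1L) * bpr
    ft <- dec[off + 1L]
    cur <- dec[off + 1L + seq_len(nc * W)]
    if (ft == 1L) {
      for (i in (nc + 1L):(nc * W)) cur[i] <- (cur[i] + cur[i - nc]) %% 256L
    } else if (ft == 2L) {
      cur <- (cur + prev) %% 256L
    } else if (ft == 3L) {
      for (i in seq_len(nc * W)) {
        left <- if (i > nc) cur[i - nc] else 0L
        cur[i] <- (cur[i] + (left + prev[i]) %/% 2L) %% 256L
      }
    } else if (ft == 4L) {
      for (i in seq_len(nc * W)) {
        left <- if (i > nc) cur[i - nc] else 0L
        ul <- if (i > nc) prev[i - nc] else 0L
        cur[i] <- (cur[i] + paeth(left, prev[i], ul)) %% 256L
      }
    } else if (ft != 0L) stop("I/O error: unknown PNG filter type ", ft)
    img[, row] <- cur
    prev <- cur
  }
  if (nc == 1L) {
    t(img) / 255                                     # (H,W)
  } else {
    aperm(array(img, c(3L, W, H)), c(3, 2, 1)) / 255 # (H,W,3)
  }
}
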