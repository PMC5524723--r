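#' Read a greyscale image from file
#'
#' Supported formats: PNG and TIFF (via the \pkg{png} and \pkg{tiff}
#' packages) and uncompressed BMP (8-bit palettized and 24/32-bit,
#' read natively). Multi-channel inputs are converted to a single channel by
#' the ITU-R 601 luma weighting \eqn{0.299 R + 0.587 G + 0.114 B}; an alpha
#' channel, if present, is ignored. Pixels are returned as integers in
#' \eqn{[0, 255]}; a save/load round trip of an 8-bit image is lossless.
#'
#' @param path Path to a `.png`, `.bmp`, `.tif`/`.tiff` file.
#' @return An integer-valued 8-bit `gray_image`.
#' @export
read_gray <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read image: file not found: %s", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    bmp = return(read_bmp_gray(path)),
    stop(sprintf("unsupported image format '.%s' for %s (supported: png, bmp, tiff)",
                 ext, path), call. = FALSE)
  )
  x <- luma_collapse(arr) * 255
  quantize_gray(gray_image(x, bit_depth = 8L, domain = "display"))
}

#' Write a greyscale image to file
#'
#' Quantizes (round half up) to 8-bit and writes PNG, TIFF or uncompressed
#' 8-bit palettized BMP according to the file extension.
#'
#' @param image Display-domain `gray_image`.
#' @param path Output path ending in `.png`, `.bmp`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_gray <- function(image, path) {
  if (!dir.exists(dirname(path))) {
    stop(sprintf("cannot write image: directory does not exist: %s",
                 dirname(path)), call. = FALSE)
  }
  q <- px(quantize_gray(as_gray_image(px(image), bit_depth = 8L)))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(q / 255, path),
    tif = ,
    tiff = tiff::writeTIFF(q / 255, path, bits.per.sample = 8L),
    bmp = write_bmp_gray(q, path),
    stop(sprintf("unsupported image format '.%s' for %s (supported: png, bmp, tiff)",
                 ext, path), call. = FALSE)
  )
  invisible(path)
}

# Collapse an array from png/tiff readers ([0,1], h x w or h x w x ch) to a
# single-channel [0,1] matrix using ITU-R 601 luma weights.
luma_collapse <- function(arr) {
  if (length(dim(arr)) == 2L) return(arr)
  ch <- dim(arr)[3]
  if (ch == 1L) return(arr[, , 1])
  if (ch == 2L) return(arr[, , 1])                 # grey + alpha
  0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
}

# --- minimal uncompressed BMP support -------------------------------------
# No installed R package covers BMP, so the subset the tool needs is read and
# written directly: BITMAPINFOHEADER, no compression (BI_RGB), 8-bit
# palettized or 24/32-bit. Rows are stored bottom-up, padded to 4 bytes.

read_u16 <- function(raw, off) as.integer(raw[off + 1]) + 256L * as.integer(raw[off + 2])
read_u32 <- function(raw, off) {
  sum(as.numeric(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
}

read_bmp_gray <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 54 || rawToChar(raw[1:2]) != "BM") {
    stop(sprintf("cannot read image: not a BMP file: %s", path), call. = FALSE)
  }
  data_off <- read_u32(raw, 10)
  hdr_size <- read_u32(raw, 14)
  if (hdr_size < 40) {
    stop(sprintf("unsupported BMP header in %s", path), call. = FALSE)
  }
  w <- read_u32(raw, 18)
  h_raw <- read_u32(raw, 22)
  top_down <- h_raw > 2^31
  h <- if (top_down) 2^32 - h_raw else h_raw
  bpp <- read_u16(raw, 28)
  compression <- read_u32(raw, 30)
  if (compression != 0 || !(bpp %in% c(8L, 24L, 32L))) {
    stop(sprintf("unsupported BMP variant in %s (need uncompressed 8/24/32-bit)",
                 path), call. = FALSE)
  }
  pal <- NULL
  if (bpp == 8L) {
    n_colors <- read_u32(raw, 46)
    if (n_colors == 0) n_colors <- 256
    pal_raw <- raw[14 + hdr_size + seq_len(4 * n_colors)]
    pal <- matrix(as.integer(pal_raw), nrow = 4)  # B, G, R, reserved
  }
  bytes_pp <- bpp %/% 8L
  row_bytes <- 4L * ((w * bytes_pp + 3L) %/% 4L)
  x <- matrix(0, h, w)
  for (r in seq_len(h)) {
    off <- data_off + (r - 1L) * row_bytes
    row <- as.integer(raw[off + seq_len(w * bytes_pp)])
    vals <- if (bpp == 8L) {
      idx <- row + 1L
      0.299 * pal[3, idx] + 0.587 * pal[2, idx] + 0.114 * pal[1, idx]
    } else {
      b <- row[seq(1L, by = bytes_pp, length.out = w)]
      g <- row[seq(2L, by = bytes_pp, length.out = w)]
      rr <- row[seq(3L, by = bytes_pp, length.out = w)]
      0.299 * rr + 0.587 * g + 0.114 * b
    }
    tgt <- if (top_down) r else h - r + 1L
    x[tgt, ] <- vals
  }
  quantize_gray(gray_image(x, bit_depth = 8L, domain = "display"))
}

write_u16 <- function(con, v) writeBin(as.integer(v), con, size = 2, endian = "little")
write_u32 <- function(con, v) writeBin(as.integer(v), con, size = 4, endian = "little")

write_bmp_gray <- function(x, path) {
  h <- nrow(x); w <- ncol(x)
  pad <- (4L - w %% 4L) %% 4L
  data_size <- (w + pad) * h
  offset <- 14L + 40L + 1024L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("BM"), con)
  write_u32(con, offset + data_size)
  write_u32(con, 0L)
  write_u32(con, offset)
  write_u32(con, 40L)                 # BITMAPINFOHEADER
  write_u32(con, w)
  write_u32(con, h)
  write_u16(con, 1L)                  # planes
  write_u16(con, 8L)                  # bits per pixel
  write_u32(con, 0L)                  # BI_RGB
  write_u32(con, data_size)
  write_u32(con, 2835L)               # 72 dpi
  write_u32(con, 2835L)
  write_u32(con, 256L)
  write_u32(con, 0L)
  writeBin(as.raw(rep(0:255, each = 4) * rep(c(1L, 1L, 1L, 0L), 256)), con)
  zero <- as.raw(rep(0L, pad))
  for (r in h:1) {
    writeBin(as.raw(x[r, ]), con)
    if (pad > 0L) writeBin(zero, con)
  }
  invisible(path)
}
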