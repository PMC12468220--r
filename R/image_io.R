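## Images are plain numeric arrays: a matrix (h x w) for single-channel data in
## [0,1], or an h x w x 3 array for RGB in [0,1].  Binary masks are logical
## matrices.  Grayscale *levels* (0..255 integers) are numeric matrices carrying
## the attribute "levels256" so histogram code can insist on quantized input.

stop_if_empty <- function(x, what = "image") {
  d <- dim(x)
  if (is.null(d) || length(d) < 2L || d[1L] < 1L || d[2L] < 1L)
    stop(what, " must have height >= 1 and width >= 1", call. = FALSE)
  invisible(x)
}

assert_unit_range <- function(x, what = "image", tol = 1e-8) {
  if (anyNA(x)) stop(what, " contains NA values", call. = FALSE)
  r <- range(x)
  if (r[1L] < -tol || r[2L] > 1 + tol)
    stop(what, " values must lie in [0, 1]; observed range [",
         signif(r[1L], 4), ", ", signif(r[2L], 4), "]", call. = FALSE)
  invisible(x)
}

is_rgb_array <- function(x) is.array(x) && length(dim(x)) == 3L && dim(x)[3L] == 3L

## channel slice that never drops the matrix shape (1x1 images included)
slice_ch <- function(img, k) matrix(img[, , k], dim(img)[1L], dim(img)[2L])

assert_rgb <- function(img, what = "img") {
  stop_if_empty(img, what)
  if (!is_rgb_array(img))
    stop(what, " must be an h x w x 3 RGB array", call. = FALSE)
  assert_unit_range(img, what)
  invisible(img)
}

assert_channel <- function(channel, what = "channel") {
  stop_if_empty(channel, what)
  if (!is.matrix(channel))
    stop(what, " must be a single-channel matrix", call. = FALSE)
  assert_unit_range(channel, what)
  invisible(channel)
}

assert_mask <- function(mask, what = "mask") {
  stop_if_empty(mask, what)
  if (!is.matrix(mask) || !is.logical(mask))
    stop(what, " must be a logical matrix", call. = FALSE)
  invisible(mask)
}

## 8-bit quantization used at serialization time: round-half-to-even (base R
## round()) after clamping, per the package-wide convention that all pipeline
## arithmetic stays in float and [0,255] appears only in files.
quantize_8bit <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  round(x * 255)
}

#' Read an 8-bit raster image
#'
#' Loads a PNG, TIFF or uncompressed 24-bit BMP image and returns it
#' normalized to \[0,1\]: an `h x w` matrix for grayscale input or an
#' `h x w x 3` array for RGB. An alpha channel, if present, is dropped
#' with a warning.
#'
#' @param path Path to a `.png`, `.tif`/`.tiff` or `.bmp` file.
#' @return Numeric matrix or `h x w x 3` array with values in \[0,1\].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    bmp  = read_bmp(path),
    stop("unsupported image format: .", ext, " (PNG, TIFF, BMP supported)",
         call. = FALSE)
  )
  if (is.array(img) && length(dim(img)) == 3L) {
    nc <- dim(img)[3L]
    if (nc == 2L) {            # gray + alpha
      warning("dropping alpha channel of ", basename(path))
      img <- img[, , 1L]
    } else if (nc == 4L) {     # RGBA
      warning("dropping alpha channel of ", basename(path))
      img <- img[, , 1:3, drop = FALSE]
    } else if (nc == 1L) {
      img <- img[, , 1L]
    }
  }
  stop_if_empty(img)
  img
}

#' Write an image as 8-bit PNG, TIFF or BMP
#'
#' Values are clamped to \[0,1\] and quantized to 8 bits (round-half-to-even)
#' at write time; pipeline arithmetic elsewhere stays in float.
#'
#' @param img Matrix (grayscale) or `h x w x 3` array (RGB), values in \[0,1\].
#' @param path Output path; format chosen from the extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stop_if_empty(img)
  q <- quantize_8bit(img) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(q, path),
    tif  = ,
    tiff = tiff::writeTIFF(q, path, bits.per.sample = 8L),
    bmp  = write_bmp(q, path),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  invisible(path)
}

#' Write a binary mask as an 8-bit \{0,255\} image
#'
#' @param mask Logical matrix, `TRUE` = nucleus/foreground.
#' @param path Output path (PNG/TIFF/BMP).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  assert_mask(mask)
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  write_image(m, path)
}

#' Read a binary mask written by [write_mask()]
#'
#' Any pixel at or above mid-gray is foreground; RGB input is converted by
#' luminance first.
#'
#' @param path Image path.
#' @return Logical matrix.
#' @export
read_mask <- function(path) {
  img <- read_image(path)
  if (is_rgb_array(img)) img <- luminance(img)
  img >= 0.5
}

## ---- minimal 24-bit uncompressed BMP support (no installed reader) ----

read_bmp <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readBin(con, "raw", 2L)
  if (!identical(as.integer(magic), c(0x42L, 0x4DL)))
    stop("not a BMP file: ", path, call. = FALSE)
  readBin(con, "integer", 2L, size = 4L)               # file size, reserved
  offset <- readBin(con, "integer", 1L, size = 4L)
  hdr_size <- readBin(con, "integer", 1L, size = 4L)
  if (hdr_size < 40L) stop("unsupported BMP header", call. = FALSE)
  w <- readBin(con, "integer", 1L, size = 4L)
  h <- readBin(con, "integer", 1L, size = 4L)
  readBin(con, "integer", 1L, size = 2L)               # planes
  bpp <- readBin(con, "integer", 1L, size = 2L)
  compression <- readBin(con, "integer", 1L, size = 4L)
  if (bpp != 24L || compression != 0L)
    stop("only uncompressed 24-bit BMP is supported", call. = FALSE)
  seek(con, offset)
  row_bytes <- ((w * 3L + 3L) %/% 4L) * 4L
  raw <- readBin(con, "raw", row_bytes * abs(h))
  flip <- h > 0L
  h <- abs(h)
  img <- array(0, c(h, w, 3L))
  v <- as.integer(raw)
  for (r in seq_len(h)) {
    row <- v[((r - 1L) * row_bytes + 1L):((r - 1L) * row_bytes + w * 3L)]
    i <- if (flip) h - r + 1L else r
    img[i, , 3L] <- row[seq(1L, by = 3L, length.out = w)]   # B
    img[i, , 2L] <- row[seq(2L, by = 3L, length.out = w)]   # G
    img[i, , 1L] <- row[seq(3L, by = 3L, length.out = w)]   # R
  }
  img / 255
}

write_bmp <- function(img, path) {
  if (is.matrix(img)) img <- array(rep(img, 3L), c(dim(img), 3L))
  h <- dim(img)[1L]; w <- dim(img)[2L]
  px <- quantize_8bit(img)
  row_bytes <- ((w * 3L + 3L) %/% 4L) * 4L
  data_size <- row_bytes * h
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(as.raw(c(0x42, 0x4D)), con)
  writeBin(as.integer(54L + data_size), con, size = 4L)
  writeBin(0L, con, size = 4L)
  writeBin(54L, con, size = 4L)
  writeBin(40L, con, size = 4L)
  writeBin(as.integer(w), con, size = 4L)
  writeBin(as.integer(h), con, size = 4L)   # positive => bottom-up rows
  writeBin(1L, con, size = 2L)
  writeBin(24L, con, size = 2L)
  writeBin(0L, con, size = 4L)
  writeBin(as.integer(data_size), con, size = 4L)
  writeBin(c(2835L, 2835L, 0L, 0L), con, size = 4L)
  pad <- raw(row_bytes - w * 3L)
  for (r in seq(h, 1L)) {
    row <- as.raw(as.vector(rbind(px[r, , 3L], px[r, , 2L], px[r, , 1L])))
    writeBin(c(row, pad), con)
  }
  invisible(path)
}
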