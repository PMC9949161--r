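# Minimal multi-page TIFF I/O.
#
# No TIFF package ships with the supported toolchain, so the package carries
# its own reader/writer for the small subset of baseline TIFF the pipeline
# exchanges: uncompressed, single-sample (grayscale), 16-bit unsigned or
# 32-bit float, one or more pages.  Files written here are readable by
# tifffile/ImageJ and vice versa (round-trip is exercised in the test suite
# against an independent reader).

.tiff_tag <- function(con, tag, type, count, value) {
  # type 3 = SHORT, 4 = LONG
  writeBin(as.integer(tag), con, size = 2, endian = "little")
  writeBin(as.integer(type), con, size = 2, endian = "little")
  writeBin(as.integer(count), con, size = 4, endian = "little")
  if (type == 3L) {
    writeBin(as.integer(value), con, size = 2, endian = "little")
    writeBin(0L, con, size = 2, endian = "little")
  } else {
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
}

#' Write an image stack as a multi-page TIFF
#'
#' @param x a numeric matrix (one page) or a `T x H x W` array (one page per
#'   leading index).
#' @param path output file path.
#' @param bits 32 (IEEE float, default) or 16 (unsigned integer; values must
#'   lie in `[0, 65535]` and are rounded).
#' @return `path`, invisibly.
#' @seealso [read_tiff()]
#' @export
write_tiff <- function(x, path, bits = 32L) {
  if (is.matrix(x)) x <- array(x, dim = c(1L, dim(x)))
  if (length(dim(x)) != 3L) stopf("x must be a matrix or a T x H x W array")
  if (!bits %in% c(16L, 32L)) stopf("bits must be 16 or 32")
  check_finite(x, "image data")
  n <- dim(x)[1]; h <- dim(x)[2]; w <- dim(x)[3]
  bytes_px <- bits / 8L
  strip_bytes <- h * w * bytes_px
  n_tags <- 10L
  ifd_bytes <- 2L + n_tags * 12L + 4L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  first_ifd <- 8L + n * strip_bytes
  writeBin(as.integer(first_ifd), con, size = 4, endian = "little")
  # pixel data, page by page, rows in row-major order
  for (k in seq_len(n)) {
    v <- as.vector(t(x[k, , ]))
    if (bits == 32L) {
      writeBin(as.numeric(v), con, size = 4, endian = "little")
    } else {
      iv <- as.integer(round(v))
      if (any(iv < 0L | iv > 65535L)) stopf("16-bit output requires values in [0, 65535]")
      iv[iv > 32767L] <- iv[iv > 32767L] - 65536L  # two's complement low bytes
      writeBin(iv, con, size = 2, endian = "little")
    }
  }
  for (k in seq_len(n)) {
    strip_off <- 8L + (k - 1L) * strip_bytes
    writeBin(n_tags, con, size = 2, endian = "little")
    .tiff_tag(con, 256L, 4L, 1L, w)            # ImageWidth
    .tiff_tag(con, 257L, 4L, 1L, h)            # ImageLength
    .tiff_tag(con, 258L, 3L, 1L, bits)         # BitsPerSample
    .tiff_tag(con, 259L, 3L, 1L, 1L)           # Compression: none
    .tiff_tag(con, 262L, 3L, 1L, 1L)           # Photometric: BlackIsZero
    .tiff_tag(con, 273L, 4L, 1L, strip_off)    # StripOffsets
    .tiff_tag(con, 277L, 3L, 1L, 1L)           # SamplesPerPixel
    .tiff_tag(con, 278L, 4L, 1L, h)            # RowsPerStrip
    .tiff_tag(con, 279L, 4L, 1L, strip_bytes)  # StripByteCounts
    .tiff_tag(con, 339L, 3L, 1L, if (bits == 32L) 3L else 1L)  # SampleFormat
    next_ifd <- if (k < n) first_ifd + k * ifd_bytes else 0L
    writeBin(as.integer(next_ifd), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a multi-page TIFF into a `T x H x W` array
#'
#' Supports the baseline subset written by [write_tiff()]: uncompressed
#' grayscale, 8/16-bit unsigned or 32-bit float, little- or big-endian,
#' arbitrary strip layout.
#'
#' @param path file path.
#' @return numeric array of dimension `n_pages x H x W`.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8L) stopf("not a TIFF file: %s", path)
  endian <- if (rawToChar(raw[1:2]) == "II") "little"
            else if (rawToChar(raw[1:2]) == "MM") "big"
            else stopf("not a TIFF file: %s", path)
  u16 <- function(off) readBin(raw[(off + 1):(off + 2)], "integer", size = 2,
                               signed = FALSE, endian = endian)
  u32 <- function(off) readBin(raw[(off + 1):(off + 4)], "integer", size = 4,
                               endian = endian)
  if (u16(2) != 42L) stopf("bad TIFF magic in %s", path)
  ifd_off <- u32(4)
  pages <- list()
  while (ifd_off != 0L) {
    n_tags <- u16(ifd_off)
    tags <- list()
    for (i in seq_len(n_tags)) {
      e <- ifd_off + 2L + (i - 1L) * 12L
      tag <- u16(e); type <- u16(e + 2L); count <- u32(e + 4L)
      val_off <- e + 8L
      if (!type %in% c(1L, 3L, 4L)) next  # only BYTE/SHORT/LONG tags matter here
      sz <- c(1L, 1L, 2L, 4L)[type]
      off <- if (count * sz <= 4L) val_off else u32(val_off)
      tags[[as.character(tag)]] <- vapply(seq_len(count), function(j) {
        o <- off + (j - 1L) * sz
        if (sz == 2L) u16(o) else if (sz == 4L) u32(o)
        else as.integer(raw[o + 1L])
      }, integer(1))
    }
    g <- function(t, default = NULL) tags[[as.character(t)]] %||% default
    w <- g(256L)[1]; h <- g(257L)[1]
    bits <- g(258L, 8L)[1]
    if (g(259L, 1L)[1] != 1L) stopf("compressed TIFF not supported: %s", path)
    fmt <- g(339L, 1L)[1]
    offs <- g(273L); counts <- g(279L, h * w * bits / 8L)
    rows_per_strip <- g(278L, h)[1]
    if (g(277L, 1L)[1] != 1L) stopf("multi-sample TIFF not supported: %s", path)
    px <- numeric(0)
    for (s in seq_along(offs)) {
      nb <- counts[min(s, length(counts))]
      seg <- raw[(offs[s] + 1L):(offs[s] + nb)]
      px <- c(px, switch(
        paste(bits, fmt),
        "32 3" = readBin(seg, "numeric", n = nb / 4L, size = 4, endian = endian),
        "16 1" = readBin(seg, "integer", n = nb / 2L, size = 2, signed = FALSE,
                         endian = endian),
        "8 1"  = as.numeric(seg),
        stopf("unsupported TIFF sample format (bits=%d, fmt=%d)", bits, fmt)
      ))
    }
    pages[[length(pages) + 1L]] <- t(matrix(px[seq_len(h * w)], nrow = w, ncol = h))
    ifd_off <- u32(ifd_off + 2L + n_tags * 12L)
  }
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  out <- array(0, dim = c(length(pages), h, w))
  for (k in seq_along(pages)) out[k, , ] <- pages[[k]]
  out
}
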