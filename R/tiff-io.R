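## Minimal baseline TIFF I/O: little-endian, uncompressed, grayscale,
## 8- or 16-bit, one strip per page.  No R TIFF reader is available in the
## target environment, so the subset of the format this package emits is
## implemented here and round-trip tested.

TIFF_TAGS <- c(width = 256L, height = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, spp = 277L,
               rows_per_strip = 278L, strip_bytes = 279L, sample_format = 339L)

#' Write a grayscale image stack as multi-page TIFF
#'
#' Encodes each frame as one uncompressed 16-bit (or 8-bit) grayscale page.
#' Intensities in \[0, 1\] are scaled to the full integer range and rounded,
#' so a round trip quantizes to `1/(2^bits - 1)` steps.
#'
#' @param stack an [image_stack()], or a list of numeric matrices in \[0, 1\].
#' @param path output file path.
#' @param bits bits per sample, 8 or 16 (default).
#' @return `path`, invisibly.
#' @seealso [read_tiff_stack()]
#' @export
write_tiff_stack <- function(stack, path, bits = 16L) {
  frames <- if (inherits(stack, "image_stack")) stack$frames else stack
  stopifnot(bits %in% c(8L, 16L), length(frames) >= 1L)
  maxval <- 2^bits - 1
  con <- file(path, "wb")
  on.exit(close(con))
  w <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  # header: II, magic 42, offset of first IFD (filled after pixel data)
  writeBin(charToRaw("II"), con)
  w(42L, 2)
  n <- length(frames)
  h <- nrow(frames[[1]]); wd <- ncol(frames[[1]])
  bytes_pp <- bits / 8
  strip_len <- h * wd * bytes_pp
  data_start <- 8L
  ifd_start <- data_start + n * strip_len
  w(ifd_start, 4)
  # pixel data, row-major (TIFF scanline order)
  for (fr in frames) {
    v <- round(pmin(pmax(t(fr), 0), 1) * maxval)
    w(as.vector(v), bytes_pp)
  }
  # one IFD per page; 10 entries each
  n_entries <- 10L
  ifd_size <- 2L + n_entries * 12L + 4L
  for (i in seq_len(n)) {
    entry <- function(tag, type, count, value) {
      w(tag, 2); w(type, 2); w(count, 4)
      if (type == 3L) { w(value, 2); w(0L, 2) } else w(value, 4)
    }
    w(n_entries, 2)
    entry(TIFF_TAGS[["width"]], 3L, 1L, wd)
    entry(TIFF_TAGS[["height"]], 3L, 1L, h)
    entry(TIFF_TAGS[["bits"]], 3L, 1L, bits)
    entry(TIFF_TAGS[["compression"]], 3L, 1L, 1L)
    entry(TIFF_TAGS[["photometric"]], 3L, 1L, 1L)  # BlackIsZero
    entry(TIFF_TAGS[["strip_offsets"]], 4L, 1L, data_start + (i - 1L) * strip_len)
    entry(TIFF_TAGS[["spp"]], 3L, 1L, 1L)
    entry(TIFF_TAGS[["rows_per_strip"]], 3L, 1L, h)
    entry(TIFF_TAGS[["strip_bytes"]], 4L, 1L, strip_len)
    entry(TIFF_TAGS[["sample_format"]], 3L, 1L, 1L)
    next_ifd <- if (i < n) ifd_start + i * ifd_size else 0L
    w(next_ifd, 4)
  }
  invisible(path)
}

#' Read a grayscale multi-page TIFF into an image stack
#'
#' Supports the baseline subset written by [write_tiff_stack()]:
#' little-endian, uncompressed, single-sample grayscale, 8 or 16 bits.
#'
#' @param path TIFF file path.
#' @param times acquisition times in minutes (default 10-min spacing).
#' @return An [image_stack()] with intensities rescaled to \[0, 1\].
#' @export
read_tiff_stack <- function(path, times = NULL) {
  raw <- readBin(path, "raw", file.size(path))
  u <- function(off, size) {  # little-endian unsigned int at 1-based offset
    sum(as.integer(raw[off + seq_len(size) - 1L]) * 256^(seq_len(size) - 1L))
  }
  if (rawToChar(raw[1:2]) != "II" || u(3L, 2L) != 42L)
    stop("not a little-endian TIFF file", call. = FALSE)
  ifd_off <- u(5L, 4L)
  frames <- list()
  while (ifd_off != 0L) {
    n_entries <- u(ifd_off + 1L, 2L)
    tags <- list()
    for (k in seq_len(n_entries)) {
      e <- ifd_off + 2L + (k - 1L) * 12L + 1L
      tag <- u(e, 2L); type <- u(e + 2L, 2L)
      val <- if (type == 3L) u(e + 8L, 2L) else u(e + 8L, 4L)
      tags[[as.character(tag)]] <- val
    }
    g <- function(id, default = NULL) {
      v <- tags[[as.character(id)]]
      if (is.null(v)) default else v
    }
    if (g(TIFF_TAGS[["compression"]], 1L) != 1L)
      stop("only uncompressed TIFF is supported", call. = FALSE)
    bits <- g(TIFF_TAGS[["bits"]], 1L)
    if (!bits %in% c(8L, 16L))
      stop("only 8/16-bit grayscale TIFF is supported", call. = FALSE)
    wd <- g(TIFF_TAGS[["width"]]); h <- g(TIFF_TAGS[["height"]])
    off <- g(TIFF_TAGS[["strip_offsets"]])
    bytes_pp <- bits / 8
    npx <- wd * h
    px <- raw[off + seq_len(npx * bytes_pp)]
    vals <- if (bits == 8L) as.integer(px) else {
      m <- matrix(as.integer(px), nrow = 2)
      m[1, ] + 256L * m[2, ]
    }
    frames[[length(frames) + 1L]] <- t(matrix(vals / (2^bits - 1), nrow = wd))
    ifd_off <- u(ifd_off + 2L + n_entries * 12L + 1L, 4L)
  }
  if (is.null(times)) times <- seq(0, by = 10, length.out = length(frames))
  image_stack(frames, times)
}
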