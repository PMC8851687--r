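#' Minimal grayscale TIFF input/output
#'
#' A baseline TIFF 6.0 codec for the single-plane grayscale images this
#' package exchanges: little-endian, uncompressed, one strip, 8- or
#' 16-bit unsigned. It exists because no TIFF package is available in
#' the target environment; it is not a general-purpose TIFF library.
#'
#' @param path file path.
#' @param img integer matrix of non-negative pixel values (rows =
#'   image rows).
#' @param bit_depth 8 or 16.
#' @return `write_tiff()` returns `path` invisibly; `read_tiff()`
#'   returns an integer matrix.
#' @examples
#' f <- tempfile(fileext = ".tiff")
#' m <- matrix(0:15, 4, 4)
#' write_tiff(f, m, bit_depth = 16)
#' identical(read_tiff(f), m)
#' @export
write_tiff <- function(path, img, bit_depth = 16L) {
  if (!is.matrix(img)) stop("`img` must be a matrix", call. = FALSE)
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16", call. = FALSE)
  maxval <- 2^bit_depth - 1
  v <- as.integer(round(img))
  if (anyNA(v) || any(v < 0L) || any(v > maxval))
    stop("pixel values out of range for bit depth", call. = FALSE)
  nr <- nrow(img); nc <- ncol(img)
  bytes_per <- bit_depth / 8L
  data_len <- nr * nc * bytes_per
  ifd_offset <- 8L + data_len
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(ifd_offset), con, size = 4, endian = "little")
  # pixel data, row-major single strip
  writeBin(as.integer(t(img)), con, size = bytes_per, endian = "little")
  tags <- list(
    # tag, type (3 = SHORT, 4 = LONG), count, value
    c(256L, 4L, 1L, nc),          # ImageWidth
    c(257L, 4L, 1L, nr),          # ImageLength
    c(258L, 3L, 1L, bit_depth),   # BitsPerSample
    c(259L, 3L, 1L, 1L),          # Compression: none
    c(262L, 3L, 1L, 1L),          # Photometric: BlackIsZero
    c(273L, 4L, 1L, 8L),          # StripOffsets
    c(277L, 3L, 1L, 1L),          # SamplesPerPixel
    c(278L, 4L, 1L, nr),          # RowsPerStrip
    c(279L, 4L, 1L, data_len)     # StripByteCounts
  )
  writeBin(length(tags), con, size = 2, endian = "little")
  for (tg in tags) {
    writeBin(as.integer(tg[1]), con, size = 2, endian = "little")
    writeBin(as.integer(tg[2]), con, size = 2, endian = "little")
    writeBin(as.integer(tg[3]), con, size = 4, endian = "little")
    if (tg[2] == 3L) { # SHORT left-justified in the 4-byte value slot
      writeBin(as.integer(tg[4]), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(tg[4]), con, size = 4, endian = "little")
    }
  }
  writeBin(0L, con, size = 4, endian = "little") # no next IFD
  invisible(path)
}

#' @rdname write_tiff
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8 || rawToChar(raw[1:2]) != "II")
    stop("not a little-endian TIFF", call. = FALSE)
  u16 <- function(off) as.integer(raw[off + 1]) + 256L * as.integer(raw[off + 2])
  u32 <- function(off) {
    sum(as.numeric(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
  }
  ifd <- u32(4)
  n_tags <- u16(ifd)
  tags <- list()
  for (i in seq_len(n_tags)) {
    base <- ifd + 2 + (i - 1) * 12
    tag <- u16(base)
    type <- u16(base + 2)
    val <- if (type == 3L) u16(base + 8) else u32(base + 8)
    tags[[as.character(tag)]] <- val
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop("missing TIFF tag ", tag, call. = FALSE)
      default
    } else v
  }
  if (need(259, 1) != 1) stop("compressed TIFF not supported", call. = FALSE)
  nc <- need(256); nr <- need(257)
  bit_depth <- need(258, 8)
  off <- need(273)
  bytes_per <- bit_depth / 8
  vals <- readBin(raw[(off + 1):(off + nr * nc * bytes_per)], "integer",
                  n = nr * nc, size = bytes_per, signed = FALSE,
                  endian = "little")
  matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
}
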