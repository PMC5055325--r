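# Minimal baseline TIFF codec for the volume container: multi-page, 16-bit
# grayscale, single strip per page, uncompressed, little-endian. No general
# TIFF support is attempted or needed -- this reads what write_tiff16() writes
# (plus any conforming file with the same layout).

.tiff_tag <- function(id, type, count, value) list(id = id, type = type,
                                                   count = count, value = value)

write_tiff16 <- function(pages, path) {
  # pages: list of integer matrices (values 0..65535), all the same dim
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeChar("II", con, eos = NULL); w2(42L)
  nr <- nrow(pages[[1]]); nc <- ncol(pages[[1]])
  nbytes <- nr * nc * 2L
  n_tags <- 8L
  ifd_size <- 2L + n_tags * 12L + 4L
  # layout: header(8) then per page [pixel strip][IFD]
  strip_off <- function(i) 8L + (i - 1L) * (nbytes + ifd_size)
  ifd_off <- function(i) strip_off(i) + nbytes
  w4(ifd_off(1L))
  for (i in seq_along(pages)) {
    m <- pages[[i]]
    stopifnot(nrow(m) == nr, ncol(m) == nc)
    # TIFF stores row-major (rows of the image); R matrices are column-major
    vals <- as.integer(t(m))
    vals[vals > 32767L] <- vals[vals > 32767L] - 65536L  # two's complement for writeBin
    writeBin(vals, con, size = 2, endian = "little")
    wtag <- function(id, type, count, value) { w2(id); w2(type); w4(count); w4(value) }
    w2(n_tags)
    wtag(256L, 3L, 1L, nc)              # ImageWidth
    wtag(257L, 3L, 1L, nr)              # ImageLength
    wtag(258L, 3L, 1L, 16L)             # BitsPerSample
    wtag(259L, 3L, 1L, 1L)              # Compression = none
    wtag(262L, 3L, 1L, 1L)              # Photometric = BlackIsZero
    wtag(273L, 4L, 1L, strip_off(i))    # StripOffsets
    wtag(278L, 3L, 1L, nr)              # RowsPerStrip
    wtag(279L, 4L, 1L, nbytes)          # StripByteCounts
    w4(if (i < length(pages)) ifd_off(i + 1L) else 0L)
  }
  invisible(path)
}

read_tiff16 <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  u16 <- function(off) as.integer(raw[off + 1L]) + 256L * as.integer(raw[off + 2L])
  u32 <- function(off) as.integer(raw[off + 1L]) + 256 * as.integer(raw[off + 2L]) +
    65536 * as.integer(raw[off + 3L]) + 16777216 * as.integer(raw[off + 4L])
  if (rawToChar(raw[1:2]) != "II" || u16(2L) != 42L)
    stop("not a little-endian TIFF file")
  pages <- list()
  ifd <- u32(4L)
  while (ifd != 0) {
    n_tags <- u16(ifd)
    tags <- list()
    for (t in seq_len(n_tags)) {
      off <- ifd + 2L + (t - 1L) * 12L
      id <- u16(off); type <- u16(off + 2L)
      val <- if (type == 3L) u16(off + 8L) else u32(off + 8L)
      tags[[as.character(id)]] <- val
    }
    need <- c("256", "257", "273", "279")
    if (!all(need %in% names(tags))) stop("unsupported TIFF: missing required tags")
    if (!is.null(tags[["259"]]) && tags[["259"]] != 1L)
      stop("unsupported TIFF: compressed data")
    if (!is.null(tags[["258"]]) && tags[["258"]] != 16L)
      stop("unsupported TIFF: not 16-bit")
    nc <- tags[["256"]]; nr <- tags[["257"]]
    soff <- tags[["273"]]; sbytes <- tags[["279"]]
    if (sbytes != nr * nc * 2L) stop("unsupported TIFF: multiple strips")
    if (soff + sbytes > length(raw)) stop("corrupt TIFF: strip out of range")
    bytes <- raw[(soff + 1L):(soff + sbytes)]
    v <- readBin(bytes, "integer", n = nr * nc, size = 2, signed = FALSE,
                 endian = "little")
    pages[[length(pages) + 1L]] <- matrix(v, nrow = nr, ncol = nc, byrow = TRUE)
    ifd <- u32(ifd + 2L + n_tags * 12L)
  }
  pages
}
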