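# Minimal baseline TIFF support: uncompressed 16-bit grayscale,
# little-endian, one strip per page. No TIFF package ships with the
# target environment, and the synthetic stacks only ever need this one
# baseline layout, so the format is read and written directly.

tiff_tag <- function(id, type, count, value) {
  # returns the 12 raw bytes of one IFD entry; `value` must fit inline
  con <- raw(0)
  w16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
  c(w16(id), w16(type), w32(count),
    if (type == 3) c(w16(value), w16(0)) else w32(value))
}

#' Write a 16-bit grayscale multi-page TIFF
#'
#' Baseline uncompressed little-endian TIFF, one page per matrix, one
#' strip per page. Values are clamped to `[0, 65535]` and rounded.
#'
#' @param pages A numeric matrix or list of equally-sized matrices.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(pages, path) {
  if (is.matrix(pages)) pages <- list(pages)
  fl_check(length(pages) >= 1 && all(vapply(pages, is.matrix, logical(1))),
           "pages must be a matrix or list of matrices")
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  fl_check(all(vapply(pages, function(p) nrow(p) == h && ncol(p) == w,
                      logical(1))), "all pages must share dimensions")
  n <- length(pages)
  data_bytes <- as.integer(2 * h * w)
  # layout: 8-byte header, then per page [pixel data][IFD]
  ifd_bytes <- 2 + 8 * 12 + 4
  offsets_data <- integer(n)
  offsets_ifd <- integer(n)
  pos <- 8
  for (i in seq_len(n)) {
    offsets_data[i] <- pos
    offsets_ifd[i] <- pos + data_bytes
    pos <- pos + data_bytes + ifd_bytes
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(as.integer(42), con, size = 2, endian = "little")
  writeBin(as.integer(offsets_ifd[1]), con, size = 4, endian = "little")
  for (i in seq_len(n)) {
    px <- pages[[i]]
    px <- round(pmin(pmax(px, 0), 65535))
    # row-major pixel order: transpose the column-major R matrix
    vals <- as.integer(t(px))
    # writeBin has no unsigned 16-bit: map [32768, 65535] to negatives
    vals <- ifelse(vals > 32767L, vals - 65536L, vals)
    writeBin(vals, con, size = 2, endian = "little")
    writeBin(as.integer(8), con, size = 2, endian = "little")  # 8 entries
    for (tag in list(
      tiff_tag(256, 3, 1, w),              # ImageWidth
      tiff_tag(257, 3, 1, h),              # ImageLength
      tiff_tag(258, 3, 1, 16),             # BitsPerSample
      tiff_tag(259, 3, 1, 1),              # Compression: none
      tiff_tag(262, 3, 1, 1),              # Photometric: BlackIsZero
      tiff_tag(273, 4, 1, offsets_data[i]),# StripOffsets
      tiff_tag(278, 3, 1, h),              # RowsPerStrip
      tiff_tag(279, 4, 1, data_bytes)))    # StripByteCounts
      writeBin(tag, con)
    next_ifd <- if (i < n) offsets_ifd[i + 1] else 0L
    writeBin(as.integer(next_ifd), con, size = 4, endian = "little")
  }
  invisible(path)
}

read_u16 <- function(raw, off, n = 1) {
  v <- readBin(raw[(off + 1):(off + 2 * n)], "integer", n = n, size = 2,
               endian = "little", signed = FALSE)
  v
}
read_u32 <- function(raw, off, n = 1) {
  v <- readBin(raw[(off + 1):(off + 4 * n)], "integer", n = n, size = 4,
               endian = "little")
  ifelse(v < 0, v + 2^32, v)
}

#' Read a 16-bit grayscale multi-page TIFF
#'
#' Supports the baseline layout written by [write_tiff()] (uncompressed,
#' little-endian, 16-bit, single sample per pixel; multiple strips are
#' accepted).
#'
#' @param path TIFF file path.
#' @return List of numeric matrices, one per page.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  fl_check(rawToChar(raw[1:2]) == "II" && read_u16(raw, 2) == 42,
           "not a little-endian TIFF", "fl_invalid_argument")
  ifd_off <- read_u32(raw, 4)
  pages <- list()
  while (ifd_off != 0) {
    n_entries <- read_u16(raw, ifd_off)
    tags <- list()
    for (k in seq_len(n_entries)) {
      e <- ifd_off + 2 + (k - 1) * 12
      id <- read_u16(raw, e)
      type <- read_u16(raw, e + 2)
      count <- read_u32(raw, e + 4)
      value <- if (type == 3 && count == 1) read_u16(raw, e + 8)
               else read_u32(raw, e + 8)
      tags[[as.character(id)]] <- list(type = type, count = count,
                                       value = value, off = e + 8)
    }
    g <- function(id, default = NULL) {
      t <- tags[[as.character(id)]]
      if (is.null(t)) return(default)
      t$value
    }
    w <- g(256); h <- g(257)
    fl_check(g(258, 16) == 16, "only 16-bit TIFFs supported")
    fl_check(g(259, 1) == 1, "only uncompressed TIFFs supported")
    so_tag <- tags[["273"]]
    sc_tag <- tags[["279"]]
    read_vec <- function(t) {
      if (t$count == 1) return(t$value)
      off <- t$value
      if (t$type == 3) read_u16(raw, off, t$count) else read_u32(raw, off, t$count)
    }
    offs <- read_vec(so_tag)
    cnts <- read_vec(sc_tag)
    vals <- integer(0)
    for (s in seq_along(offs)) {
      nv <- cnts[s] / 2
      vals <- c(vals, read_u16(raw, offs[s], nv))
    }
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = h, ncol = w,
                                          byrow = TRUE)
    ifd_off <- read_u32(raw, ifd_off + 2 + n_entries * 12)
  }
  pages
}
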