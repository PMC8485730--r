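# Minimal baseline TIFF support for multi-page grayscale 32-bit float stacks
# (little-endian, uncompressed, one strip per page). Written by hand because
# no installed R TIFF binding round-trips IEEE-float samples; the format is
# the plain baseline layout that tifffile/ImageJ produce and consume.

tiff_tag <- function(id, type, count, value) {
  list(id = id, type = type, count = count, value = value)
}

#' Write a movie as a multi-page 32-bit float grayscale TIFF
#'
#' @param movie `H x W x T` numeric array (stored as IEEE 754 single
#'   precision; values already at float precision round-trip exactly).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  d <- dim(movie)
  if (length(d) != 3) stop("movie must be an H x W x T array")
  H <- d[1]; W <- d[2]; T_len <- d[3]
  if (T_len < 1) stop("empty stack")
  con <- file(path, "wb")
  on.exit(close(con))
  endian <- "little"
  writeChar("II", con, eos = NULL)
  writeBin(42L, con, size = 2, endian = endian)
  writeBin(8L, con, size = 4, endian = endian)   # first IFD offset
  n_tags <- 10L
  ifd_size <- 2 + n_tags * 12 + 4
  data_size <- H * W * 4
  offset <- 8
  for (t in seq_len(T_len)) {
    ifd_off <- offset
    data_off <- ifd_off + ifd_size
    next_ifd <- if (t < T_len) data_off + data_size else 0L
    tags <- list(
      tiff_tag(256L, 3L, 1L, W),            # ImageWidth
      tiff_tag(257L, 3L, 1L, H),            # ImageLength
      tiff_tag(258L, 3L, 1L, 32L),          # BitsPerSample
      tiff_tag(259L, 3L, 1L, 1L),           # Compression: none
      tiff_tag(262L, 3L, 1L, 1L),           # Photometric: min-is-black
      tiff_tag(273L, 4L, 1L, data_off),     # StripOffsets
      tiff_tag(277L, 3L, 1L, 1L),           # SamplesPerPixel
      tiff_tag(278L, 3L, 1L, H),            # RowsPerStrip
      tiff_tag(279L, 4L, 1L, data_size),    # StripByteCounts
      tiff_tag(339L, 3L, 1L, 3L)            # SampleFormat: IEEE float
    )
    writeBin(n_tags, con, size = 2, endian = endian)
    for (tg in tags) {
      writeBin(tg$id, con, size = 2, endian = endian)
      writeBin(tg$type, con, size = 2, endian = endian)
      writeBin(tg$count, con, size = 4, endian = endian)
      if (tg$type == 3L) {                  # SHORT padded to 4 bytes
        writeBin(as.integer(tg$value), con, size = 2, endian = endian)
        writeBin(0L, con, size = 2, endian = endian)
      } else {
        writeBin(as.integer(tg$value), con, size = 4, endian = endian)
      }
    }
    writeBin(as.integer(next_ifd), con, size = 4, endian = endian)
    # pixel data, row-major within the page as TIFF requires
    writeBin(as.numeric(t(movie[, , t])), con, size = 4, endian = endian)
    offset <- data_off + data_size
  }
  invisible(path)
}

read_u16 <- function(raw, off, endian = "little") {
  readBin(raw[(off + 1):(off + 2)], "integer", size = 2, signed = FALSE,
          endian = endian)
}
read_u32 <- function(raw, off, endian = "little") {
  v <- readBin(raw[(off + 1):(off + 4)], "integer", size = 4, endian = endian)
  if (v < 0) v <- v + 2^32
  v
}

#' Read a multi-page grayscale 32-bit float TIFF stack
#'
#' Supports the uncompressed little-endian baseline layout written by
#' [write_movie()] (and by common scientific writers): grayscale, one sample
#' per pixel, IEEE float samples, any strip layout.
#'
#' @param path TIFF file.
#' @return `H x W x T` numeric array.
#' @export
read_movie <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8) stop("truncated TIFF: missing header")
  if (!identical(rawToChar(raw[1:2]), "II"))
    stop("only little-endian ('II') TIFF is supported")
  if (read_u16(raw, 2) != 42L) stop("not a TIFF file (bad magic)")
  ifd_off <- read_u32(raw, 4)
  pages <- list()
  page <- 0L
  while (ifd_off != 0) {
    page <- page + 1L
    if (ifd_off + 2 > length(raw))
      stop(sprintf("truncated TIFF at page %d", page))
    n_tags <- read_u16(raw, ifd_off)
    tags <- list()
    for (i in seq_len(n_tags)) {
      base <- ifd_off + 2 + (i - 1) * 12
      id <- read_u16(raw, base)
      type <- read_u16(raw, base + 2)
      count <- read_u32(raw, base + 4)
      size_of <- c(`1` = 1, `2` = 1, `3` = 2, `4` = 4)[as.character(type)]
      if (is.na(size_of)) { tags[[as.character(id)]] <- NULL; next }
      total <- size_of * count
      val_off <- if (total <= 4) base + 8 else read_u32(raw, base + 8)
      vals <- vapply(seq_len(count), function(k) {
        o <- val_off + (k - 1) * size_of
        if (size_of == 2) read_u16(raw, o) else if (size_of == 4)
          read_u32(raw, o) else as.integer(raw[o + 1])
      }, numeric(1))
      tags[[as.character(id)]] <- vals
    }
    need <- function(id) {
      v <- tags[[as.character(id)]]
      if (is.null(v)) stop(sprintf("page %d: missing TIFF tag %d", page, id))
      v
    }
    W <- need(256); H <- need(257)
    bits <- need(258); spp <- if (is.null(tags[["277"]])) 1 else tags[["277"]]
    comp <- if (is.null(tags[["259"]])) 1 else tags[["259"]]
    fmt <- if (is.null(tags[["339"]])) 1 else tags[["339"]]
    if (length(bits) != 1 || spp != 1)
      stop(sprintf("page %d: not single-channel grayscale", page))
    if (comp != 1) stop(sprintf("page %d: compressed TIFF not supported", page))
    if (bits != 32 || fmt != 3)
      stop(sprintf("page %d: expected 32-bit IEEE float samples", page))
    offs <- need(273); counts <- need(279)
    buf <- raw(0)
    for (s in seq_along(offs)) {
      if (offs[s] + counts[s] > length(raw))
        stop(sprintf("truncated TIFF at page %d", page))
      buf <- c(buf, raw[(offs[s] + 1):(offs[s] + counts[s])])
    }
    px <- readBin(buf, "numeric", n = W * H, size = 4, endian = "little")
    pages[[page]] <- t(matrix(px, W, H))   # stored row-major
    ifd_off <- read_u32(raw, ifd_off + 2 + n_tags * 12)
  }
  if (length(pages) == 0) stop("TIFF contains no pages")
  d1 <- dim(pages[[1]])
  arr <- array(0, dim = c(d1[1], d1[2], length(pages)))
  for (t in seq_along(pages)) {
    if (!identical(dim(pages[[t]]), d1))
      stop(sprintf("page %d: shape differs from page 1", t))
    arr[, , t] <- pages[[t]]
  }
  arr
}
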