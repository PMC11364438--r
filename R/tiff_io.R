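# Minimal baseline TIFF codec: uncompressed little-endian grayscale,
# 8- or 16-bit, one strip per page. Enough to round-trip the package's own
# brain stacks and to interoperate with standard readers; not a general
# TIFF implementation.

tiff_type_short <- 3L
tiff_type_long <- 4L

#' Write grayscale images as a multi-page TIFF
#'
#' Writes a list of integer matrices (pages) as an uncompressed
#' little-endian grayscale TIFF. Matrices are stored as `[x, y]` with x the
#' image width: page `p`, pixel row `r`, column `c` maps to `pages[[p]][c, r]`.
#'
#' @param pages list of numeric matrices with values in `[0, 2^bits - 1]`
#'   (values are rounded).
#' @param path output file.
#' @param bits 8 or 16 bits per sample.
#' @return `path`, invisibly.
#' @export
write_tiff_pages <- function(pages, path, bits = 16L) {
  if (!is.list(pages) || !length(pages)) stop_invalid("`pages` must be a non-empty list")
  if (!bits %in% c(8L, 16L)) stop_invalid("`bits` must be 8 or 16")
  dims <- dim(pages[[1]])
  if (any(!vapply(pages, function(p) is.matrix(p) && all(dim(p) == dims),
                  logical(1)))) {
    stop_invalid("all pages must be matrices of identical dimension")
  }
  width <- dims[1]
  height <- dims[2]
  maxval <- 2^bits - 1
  bytes_pp <- bits / 8
  strip_len <- width * height * bytes_pp

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  first_ifd <- 8L + strip_len # header, then page 1 data
  writeBin(as.integer(first_ifd), con, size = 4, endian = "little")

  n_entries <- 8L
  ifd_size <- 2L + n_entries * 12L + 4L
  offset <- 8L
  for (p in seq_along(pages)) {
    vals <- round(pmin(maxval, pmax(0, pages[[p]])))
    # row-major pixel order: row r = vals[, r]
    v <- as.integer(as.vector(vals)) # column-major == row-major of [c, r]
    if (bits == 8L) {
      writeBin(as.raw(v), con)
    } else {
      writeBin(v, con, size = 2, endian = "little")
    }
    strip_offset <- offset
    ifd_offset <- strip_offset + strip_len
    next_ifd <- if (p < length(pages)) ifd_offset + ifd_size + strip_len else 0L
    # entries must be sorted by tag
    writeBin(n_entries, con, size = 2, endian = "little")
    write_entry <- function(tag, type, count, value) {
      writeBin(as.integer(tag), con, size = 2, endian = "little")
      writeBin(as.integer(type), con, size = 2, endian = "little")
      writeBin(as.integer(count), con, size = 4, endian = "little")
      if (type == tiff_type_short) {
        writeBin(as.integer(value), con, size = 2, endian = "little")
        writeBin(0L, con, size = 2, endian = "little")
      } else {
        writeBin(as.integer(value), con, size = 4, endian = "little")
      }
    }
    write_entry(256L, tiff_type_long, 1L, width)        # ImageWidth
    write_entry(257L, tiff_type_long, 1L, height)       # ImageLength
    write_entry(258L, tiff_type_short, 1L, bits)        # BitsPerSample
    write_entry(259L, tiff_type_short, 1L, 1L)          # Compression: none
    write_entry(262L, tiff_type_short, 1L, 1L)          # BlackIsZero
    write_entry(273L, tiff_type_long, 1L, strip_offset) # StripOffsets
    write_entry(278L, tiff_type_long, 1L, height)       # RowsPerStrip
    write_entry(279L, tiff_type_long, 1L, strip_len)    # StripByteCounts
    writeBin(as.integer(next_ifd), con, size = 4, endian = "little")
    offset <- ifd_offset + ifd_size
  }
  # note: IFD offset arithmetic assumes equal-size pages (enforced above)
  invisible(path)
}

#' Read a multi-page grayscale TIFF written by this package
#'
#' Supports uncompressed little-endian grayscale TIFFs (8/16-bit, any strip
#' layout). Returns pages as `[x, y]` matrices (x = width), the layout
#' [write_tiff_pages()] uses.
#'
#' @param path TIFF file.
#' @return List of integer matrices.
#' @export
read_tiff_pages <- function(path) {
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  u16 <- function(off) {
    as.integer(raw_all[off + 1]) + 256L * as.integer(raw_all[off + 2])
  }
  u32 <- function(off) {
    as.numeric(as.integer(raw_all[off + 1])) +
      256 * as.integer(raw_all[off + 2]) +
      65536 * as.integer(raw_all[off + 3]) +
      16777216 * as.integer(raw_all[off + 4])
  }
  if (rawToChar(raw_all[1:2]) != "II" || u16(2) != 42L) {
    stop_invalid("not a little-endian TIFF file")
  }
  ifd <- u32(4)
  pages <- list()
  while (ifd != 0) {
    n <- u16(ifd)
    tags <- list()
    for (e in seq_len(n)) {
      base <- ifd + 2 + (e - 1) * 12
      tag <- u16(base)
      type <- u16(base + 2)
      count <- u32(base + 4)
      value <- if (type == tiff_type_short && count == 1) u16(base + 8) else
        u32(base + 8)
      tags[[as.character(tag)]] <- list(type = type, count = count,
                                        value = value, off = base + 8)
    }
    need <- function(tag, default = NULL) {
      t <- tags[[as.character(tag)]]
      if (is.null(t)) {
        if (is.null(default)) stop_invalid("missing TIFF tag ", tag)
        return(default)
      }
      t$value
    }
    if (need(259, 1) != 1) stop_invalid("only uncompressed TIFF supported")
    width <- need(256)
    height <- need(257)
    bits <- need(258, 8)
    if (!bits %in% c(8, 16)) stop_invalid("only 8/16-bit TIFF supported")
    spp <- need(277, 1)
    if (spp != 1) stop_invalid("only single-sample (grayscale) TIFF supported")
    so_tag <- tags[["273"]]
    sc_tag <- tags[["279"]]
    if (is.null(so_tag) || is.null(sc_tag)) stop_invalid("missing strip tags")
    read_vals <- function(t) {
      if (t$count == 1) return(t$value)
      sz <- if (t$type == tiff_type_short) 2 else 4
      off <- t$value
      vapply(seq_len(t$count), function(i) {
        if (sz == 2) u16(off + (i - 1) * 2) else u32(off + (i - 1) * 4)
      }, numeric(1))
    }
    offs <- read_vals(so_tag)
    cnts <- read_vals(sc_tag)
    buf <- raw(0)
    for (s in seq_along(offs)) {
      buf <- c(buf, raw_all[(offs[s] + 1):(offs[s] + cnts[s])])
    }
    vals <- if (bits == 8) {
      as.integer(buf)
    } else {
      readBin(buf, "integer", n = length(buf) / 2, size = 2, signed = FALSE,
              endian = "little")
    }
    pages[[length(pages) + 1]] <- matrix(vals, nrow = width, ncol = height)
    ifd <- u32(ifd + 2 + n * 12)
  }
  pages
}

#' Write / read a two-channel brain stack as channel-interleaved TIFF
#'
#' Pages are interleaved `ch1 z1, ch2 z1, ch1 z2, ...`. Intensities are
#' rounded to 16-bit integers (the simulator's intensity scale fits with
#' ample headroom).
#'
#' @param stack a [brain_stack()].
#' @param path TIFF path.
#' @param voxel_size um per voxel to assume when reading.
#' @return `write_brain_tiff`: the path, invisibly. `read_brain_tiff`: a
#'   [brain_stack()].
#' @export
write_brain_tiff <- function(stack, path) {
  if (!inherits(stack, "BrainStack")) stop_invalid("`stack` must be a BrainStack")
  d <- dim(stack$ch1)
  pages <- vector("list", 2L * d[3])
  for (z in seq_len(d[3])) {
    pages[[2 * z - 1]] <- stack$ch1[, , z]
    pages[[2 * z]] <- stack$ch2[, , z]
  }
  write_tiff_pages(pages, path, bits = 16L)
}

#' @rdname write_brain_tiff
#' @export
read_brain_tiff <- function(path, voxel_size = 1) {
  pages <- read_tiff_pages(path)
  if (length(pages) %% 2 != 0) stop_invalid("expected channel-interleaved pages")
  nz <- length(pages) / 2
  d <- c(dim(pages[[1]]), nz)
  ch1 <- array(0, d)
  ch2 <- array(0, d)
  for (z in seq_len(nz)) {
    ch1[, , z] <- pages[[2 * z - 1]]
    ch2[, , z] <- pages[[2 * z]]
  }
  brain_stack(ch1, ch2, voxel_size = voxel_size)
}
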