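#' Write a multi-page TIFF image
#'
#' Writes uncompressed baseline TIFF (little-endian). Grayscale matrices are
#' written with the given bit depth; an h x w x 3 array is written as 8-bit
#' RGB. This covers the formats the package itself produces (16-bit channel
#' stacks, 8-bit RGB display exports); it is not a general-purpose TIFF
#' library.
#'
#' @param img a matrix (one page), a list of matrices (pages), or an
#'   h x w x n array of grayscale pages; for RGB, an h x w x 3 array or a
#'   list of such arrays. Values must be non-negative integers within the
#'   chosen bit depth.
#' @param path output file path.
#' @param bits bits per sample for grayscale pages: 8 or 16. RGB is always
#'   written at 8 bits per sample.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(img, path, bits = 16L) {
  pages <- tiff_as_pages(img)
  bits <- as.integer(bits)
  if (!bits %in% c(8L, 16L)) stop("bits must be 8 or 16")
  con <- file(path, "wb")
  on.exit(close(con))
  # header: II, 42, offset of first IFD (patched per page chain)
  writeBin(charToRaw("II"), con)
  tiff_write_u16(con, 42L)
  offset_pos <- 4L              # where the pointer to the next IFD lives
  pos <- 8L                     # current end-of-file position
  writeBin(raw(4), con)         # placeholder first-IFD offset
  for (p in pages) {
    rgb <- length(dim(p)) == 3L
    pbits <- if (rgb) 8L else bits
    maxval <- 2^pbits - 1
    if (any(p < 0) || any(p > maxval)) {
      stop("pixel values outside [0, ", maxval, "] for ", pbits, "-bit output")
    }
    h <- dim(p)[1]; w <- dim(p)[2]
    # pixel data, row-major; RGB interleaved per pixel
    if (rgb) {
      v <- as.integer(aperm(p, c(3, 2, 1)))  # channel fastest, then x, then y
    } else {
      v <- as.integer(t(p))
    }
    data_off <- pos
    bytes <- if (pbits == 8L) as.raw(v) else tiff_u16_raw(v)
    writeBin(bytes, con)
    pos <- pos + length(bytes)
    if (pos %% 2L == 1L) { writeBin(raw(1), con); pos <- pos + 1L }
    ifd_off <- pos
    # patch previous next-IFD pointer
    seek(con, offset_pos, rw = "write")
    writeBin(tiff_u32_raw(ifd_off), con)
    seek(con, pos, rw = "write")
    spp <- if (rgb) 3L else 1L
    entries <- list(
      tiff_entry(256L, 3L, w),                       # ImageWidth
      tiff_entry(257L, 3L, h),                       # ImageLength
      tiff_entry(258L, 3L, rep(pbits, spp)),         # BitsPerSample
      tiff_entry(259L, 3L, 1L),                      # Compression: none
      tiff_entry(262L, 3L, if (rgb) 2L else 1L),     # Photometric
      tiff_entry(273L, 4L, data_off),                # StripOffsets
      tiff_entry(277L, 3L, spp),                     # SamplesPerPixel
      tiff_entry(278L, 3L, h),                       # RowsPerStrip
      tiff_entry(279L, 4L, length(bytes))            # StripByteCounts
    )
    n <- length(entries)
    # out-of-line values (only BitsPerSample for RGB needs one)
    tail_off <- ifd_off + 2L + n * 12L + 4L
    blob <- raw(0)
    ent_raw <- raw(0)
    for (e in entries) {
      if (length(e$payload) > 4L) {
        ent_raw <- c(ent_raw, e$head, tiff_u32_raw(tail_off + length(blob)))
        blob <- c(blob, e$payload)
      } else {
        pay <- e$payload
        length(pay) <- 4L  # zero-pad
        ent_raw <- c(ent_raw, e$head, pay)
      }
    }
    writeBin(tiff_u16_raw(n), con)
    writeBin(ent_raw, con)
    offset_pos <- ifd_off + 2L + n * 12L
    writeBin(raw(4), con)  # next-IFD placeholder (stays 0 for last page)
    writeBin(blob, con)
    pos <- tail_off + length(blob)
    if (pos %% 2L == 1L) { writeBin(raw(1), con); pos <- pos + 1L }
  }
  invisible(path)
}

#' Read a multi-page TIFF image
#'
#' Reads the uncompressed baseline subset written by [write_tiff()]
#' (little-endian, grayscale 8/16-bit or 8-bit RGB, any strip layout).
#'
#' @param path file path.
#' @param as_array if `TRUE` and all pages share dimensions, grayscale pages
#'   are returned as an h x w x n array instead of a list.
#' @return a list of matrices (grayscale) / h x w x 3 arrays (RGB), or an
#'   array when `as_array = TRUE`.
#' @export
read_tiff <- function(path, as_array = FALSE) {
  raw_all <- readBin(path, "raw", file.info(path)$size)
  if (length(raw_all) < 8) stop("not a TIFF file (truncated): ", path)
  if (rawToChar(raw_all[1:2]) != "II" || tiff_rd_u16(raw_all, 3L) != 42L) {
    stop("not a little-endian TIFF file: ", path)
  }
  pages <- list()
  off <- tiff_rd_u32(raw_all, 5L)
  while (off != 0) {
    if (off + 2 > length(raw_all)) stop("corrupt TIFF: IFD offset out of range")
    n <- tiff_rd_u16(raw_all, off + 1L)
    tags <- list()
    for (i in seq_len(n)) {
      e <- off + 1L + 2L + (i - 1L) * 12L
      tag <- tiff_rd_u16(raw_all, e)
      typ <- tiff_rd_u16(raw_all, e + 2L)
      cnt <- tiff_rd_u32(raw_all, e + 4L)
      tags[[as.character(tag)]] <- tiff_rd_values(raw_all, e + 8L, typ, cnt)
    }
    need <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) {
        if (is.null(default)) stop("corrupt TIFF: missing tag ", tag)
        default
      } else v
    }
    w <- need(256L); h <- need(257L)
    bits <- need(258L, 1L)[1]
    if (need(259L, 1L) != 1L) stop("unsupported TIFF: compressed data")
    spp <- need(277L, 1L)
    offs <- need(273L); cnts <- need(279L)
    buf <- raw(0)
    for (k in seq_along(offs)) {
      buf <- c(buf, raw_all[(offs[k] + 1L):(offs[k] + cnts[k])])
    }
    v <- if (bits == 8L) {
      as.integer(buf)
    } else if (bits == 16L) {
      readBin(buf, "integer", n = length(buf) / 2L, size = 2L,
              signed = FALSE, endian = "little")
    } else stop("unsupported TIFF bit depth: ", bits)
    if (spp == 1L) {
      pages[[length(pages) + 1L]] <- matrix(v, nrow = h, ncol = w, byrow = TRUE)
    } else if (spp == 3L) {
      a <- array(v, dim = c(3L, w, h))
      pages[[length(pages) + 1L]] <- aperm(a, c(3L, 2L, 1L))
    } else stop("unsupported TIFF samples per pixel: ", spp)
    off <- tiff_rd_u32(raw_all, off + 1L + 2L + n * 12L)
  }
  if (as_array && length(pages) > 0 && all(vapply(pages, is.matrix, TRUE))) {
    d <- dim(pages[[1]])
    if (all(vapply(pages, function(p) identical(dim(p), d), TRUE))) {
      return(array(unlist(pages), dim = c(d, length(pages))))
    }
  }
  pages
}

# --- internal raw-level helpers (little-endian) ------------------------------

tiff_as_pages <- function(img) {
  if (is.matrix(img)) return(list(img))
  if (is.array(img) && length(dim(img)) == 3L) {
    if (dim(img)[3] == 3L) return(list(img))  # single RGB page
    return(lapply(seq_len(dim(img)[3]), function(i) img[, , i]))
  }
  if (is.list(img)) return(img)
  stop("img must be a matrix, 3-d array, or list of pages")
}

tiff_u16_raw <- function(v) {
  v <- as.integer(round(v))
  as.raw(rbind(v %% 256L, v %/% 256L))
}

tiff_u32_raw <- function(v) {
  v <- as.numeric(v)
  as.raw(rbind(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256,
               (v %/% 16777216) %% 256))
}

tiff_write_u16 <- function(con, v) writeBin(tiff_u16_raw(v), con)

tiff_entry <- function(tag, type, values) {
  # type 3 = SHORT, 4 = LONG
  payload <- if (type == 3L) tiff_u16_raw(values) else tiff_u32_raw(values)
  head <- c(tiff_u16_raw(tag), tiff_u16_raw(type), tiff_u32_raw(length(values)))
  list(head = head, payload = payload)
}

tiff_rd_u16 <- function(r, i) {
  as.integer(r[i]) + 256L * as.integer(r[i + 1L])
}

tiff_rd_u32 <- function(r, i) {
  as.numeric(r[i]) + 256 * as.numeric(r[i + 1L]) +
    65536 * as.numeric(r[i + 2L]) + 16777216 * as.numeric(r[i + 3L])
}

tiff_rd_values <- function(r, vpos, typ, cnt) {
  size <- c(1L, 1L, 2L, 4L)[typ]
  if (is.na(size)) stop("unsupported TIFF tag type: ", typ)
  total <- size * cnt
  start <- if (total > 4L) tiff_rd_u32(r, vpos) + 1L else vpos
  idx <- start + seq_len(total) - 1L
  if (size == 2L) {
    vapply(seq_len(cnt), function(k) tiff_rd_u16(r, start + (k - 1L) * 2L), 1L)
  } else if (size == 4L) {
    vapply(seq_len(cnt), function(k) tiff_rd_u32(r, start + (k - 1L) * 4L), 1)
  } else {
    as.integer(r[idx])
  }
}
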