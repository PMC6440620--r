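# Minimal self-contained PNG codec for 8-bit RGB images.
#
# Only what the synthetic-data pipeline needs: truecolour (colour type 2),
# bit depth 8, no interlacing. The IDAT stream produced by memCompress() is
# already a zlib (RFC 1950) stream, which is exactly what PNG requires, so
# the codec reduces to chunk framing, CRC-32 trailers, and scanline
# (un)filtering. Kept dependency-free on purpose: the environment guarantees
# no dedicated image package, and the 'png' package (when present) is used in
# the test suite only, as an independent oracle.

png_sig <- function() as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A))

u32_to_raw <- function(x) {
  as.raw(c(x %/% 16777216, x %/% 65536, x %/% 256, x) %% 256)
}

raw_to_u32 <- function(r) {
  sum(as.numeric(r) * c(16777216, 65536, 256, 1))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32_to_raw(length(data)), body, u32_to_raw(.crc32_cpp(body)))
}

#' Read and write 8-bit RGB PNG files
#'
#' `write_png()` writes an `H x W x 3` array of values in \[0, 255\] as a
#' truecolour 8-bit PNG; `read_png()` reads such a file back. The writer is
#' byte-deterministic: identical arrays always produce identical files. The
#' reader supports all five PNG scanline filters but only 8-bit RGB without
#' interlacing, which covers every file the package itself produces.
#'
#' @param img numeric or integer array with dimensions `c(height, width, 3)`,
#'   values in \[0, 255\] (rounded and clamped on write).
#' @param path file path.
#' @return `read_png()` returns an integer `H x W x 3` array in \[0, 255\];
#'   `write_png()` returns `path` invisibly.
#' @export
write_png <- function(img, path) {
  d <- dim(img)
  if (length(d) != 3L || d[3] != 3L) stopf("write_png() expects an H x W x 3 array")
  h <- d[1]; w <- d[2]
  px <- pmin(pmax(round(img), 0), 255)
  # interleave to R,G,B per pixel, row-major scanlines, filter byte 0 per row
  bytes <- matrix(as.integer(aperm(px, c(3L, 2L, 1L))), nrow = 3L * w, ncol = h)
  scan <- as.raw(rbind(0L, bytes))
  ihdr <- c(u32_to_raw(w), u32_to_raw(h), as.raw(c(8L, 2L, 0L, 0L, 0L)))
  out <- c(png_sig(),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", memCompress(scan, type = "gzip")),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

#' @rdname write_png
#' @export
read_png <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 8L || !identical(raw[1:8], png_sig()))
    stopf("'%s' is not a PNG file", path)
  pos <- 9L
  w <- h <- NULL
  idat <- list()
  while (pos + 7L <= length(raw)) {
    len <- raw_to_u32(raw[pos:(pos + 3L)])
    type <- rawToChar(raw[(pos + 4L):(pos + 7L)])
    data <- if (len > 0) raw[(pos + 8L):(pos + 7L + len)] else raw(0)
    if (type == "IHDR") {
      w <- raw_to_u32(data[1:4]); h <- raw_to_u32(data[5:8])
      depth <- as.integer(data[9]); ctype <- as.integer(data[10])
      if (depth != 8L || ctype != 2L || as.integer(data[13]) != 0L)
        stopf("unsupported PNG (need 8-bit RGB, non-interlaced): %s", path)
    } else if (type == "IDAT") {
      idat[[length(idat) + 1L]] <- data
    } else if (type == "IEND") break
    pos <- pos + 12L + len
  }
  if (is.null(w) || !length(idat)) stopf("malformed PNG: %s", path)
  scan <- memDecompress(do.call(c, idat), type = "gzip")
  stride <- 3L * w
  if (length(scan) != (stride + 1L) * h) stopf("corrupt PNG scanlines: %s", path)
  sm <- matrix(as.integer(scan), nrow = stride + 1L, ncol = h)
  filters <- sm[1L, ]
  rows <- sm[-1L, , drop = FALSE]
  if (any(filters != 0L)) rows <- png_unfilter(rows, filters, bpp = 3L)
  aperm(array(rows, dim = c(3L, w, h)), c(3L, 2L, 1L))
}

# Undo PNG scanline filters. `rows` is a (3W x H) integer matrix of filtered
# bytes, one column per scanline, top to bottom.
png_unfilter <- function(rows, filters, bpp) {
  stride <- nrow(rows)
  prior <- integer(stride)
  for (y in seq_along(filters)) {
    cur <- rows[, y]
    f <- filters[y]
    if (f == 0L) {
      # none
    } else if (f == 2L) {         # up
      cur <- (cur + prior) %% 256L
    } else if (f %in% c(1L, 3L, 4L)) {
      left <- integer(stride)
      for (i in seq_len(stride)) {
        a <- if (i > bpp) cur[i - bpp] else 0L
        b <- prior[i]
        cc <- if (i > bpp) prior[i - bpp] else 0L
        pred <- if (f == 1L) a
        else if (f == 3L) (a + b) %/% 2L
        else {                    # Paeth
          p <- a + b - cc
          pa <- abs(p - a); pb <- abs(p - b); pc <- abs(p - cc)
          if (pa <= pb && pa <= pc) a else if (pb <= pc) b else cc
        }
        cur[i] <- (cur[i] + pred) %% 256L
      }
    } else stopf("unknown PNG filter type %d", f)
    rows[, y] <- cur
    prior <- cur
  }
  rows
}
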