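# Minimal baseline TIFF codec (uncompressed, chunky) plus a BMP reader.
# Enough of the format for this package's needs: single-channel 8/16/32-bit
# label masks and 8/16-bit grayscale or RGB images. No external image
# library provides TIFF in this environment, and label masks must round-trip
# losslessly, so the codec is written out in full here.

write_tiff_gray <- function(mat, path, bits = NULL) {
  if (!is.matrix(mat)) stop("mat must be a matrix")
  storage.mode(mat) <- "integer"
  if (any(is.na(mat)) || any(mat < 0L)) stop("labels must be non-negative integers")
  mx <- if (length(mat)) max(mat) else 0L
  if (is.null(bits)) bits <- if (mx > 65535L) 32L else 16L
  if (!bits %in% c(8L, 16L, 32L)) stop("bits must be 8, 16 or 32")
  if (bits == 8L && mx > 255L || bits == 16L && mx > 65535L)
    stop("label values overflow a ", bits, "-bit TIFF")
  h <- nrow(mat); w <- ncol(mat)
  bytes_px <- bits %/% 8L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2L, endian = "little")
  writeBin(8L, con, size = 4L, endian = "little")
  nentry <- 9L
  data_off <- 8L + 2L + nentry * 12L + 4L
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2L, endian = "little")
    writeBin(as.integer(type), con, size = 2L, endian = "little")
    writeBin(as.integer(count), con, size = 4L, endian = "little")
    if (type == 3L) { # SHORT, left-justified in the 4-byte slot
      writeBin(as.integer(value), con, size = 2L, endian = "little")
      writeBin(0L, con, size = 2L, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4L, endian = "little")
    }
  }
  writeBin(nentry, con, size = 2L, endian = "little")
  entry(256L, 4L, 1L, w)                 # ImageWidth
  entry(257L, 4L, 1L, h)                 # ImageLength
  entry(258L, 3L, 1L, bits)              # BitsPerSample
  entry(259L, 3L, 1L, 1L)                # Compression = none
  entry(262L, 3L, 1L, 1L)                # Photometric = BlackIsZero
  entry(273L, 4L, 1L, data_off)          # StripOffsets
  entry(278L, 4L, 1L, h)                 # RowsPerStrip
  entry(279L, 4L, 1L, h * w * bytes_px)  # StripByteCounts
  entry(339L, 3L, 1L, 1L)                # SampleFormat = unsigned
  writeBin(0L, con, size = 4L, endian = "little")  # next IFD
  v <- as.integer(t(mat))                # row-major
  if (bits == 16L) v <- ifelse(v > 32767L, v - 65536L, v)  # two's complement
  writeBin(v, con, size = bytes_px, endian = "little")
  invisible(path)
}

# RGB companion writer (8/16-bit, chunky, single strip); used for
# synthetic images and fixtures
write_tiff_rgb <- function(a, path, bits = 8L) {
  stopifnot(length(dim(a)) == 3L, dim(a)[3] == 3L, bits %in% c(8L, 16L))
  storage.mode(a) <- "integer"
  h <- dim(a)[1]; w <- dim(a)[2]
  bytes_px <- bits %/% 8L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2L, endian = "little")
  writeBin(8L, con, size = 4L, endian = "little")
  nentry <- 10L
  bps_off <- 8L + 2L + nentry * 12L + 4L  # 3 SHORT values live here
  data_off <- bps_off + 6L
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2L, endian = "little")
    writeBin(as.integer(type), con, size = 2L, endian = "little")
    writeBin(as.integer(count), con, size = 4L, endian = "little")
    if (type == 3L && count == 1L) {
      writeBin(as.integer(value), con, size = 2L, endian = "little")
      writeBin(0L, con, size = 2L, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4L, endian = "little")
    }
  }
  writeBin(nentry, con, size = 2L, endian = "little")
  entry(256L, 4L, 1L, w)
  entry(257L, 4L, 1L, h)
  entry(258L, 3L, 3L, bps_off)              # BitsPerSample x3 (offset)
  entry(259L, 3L, 1L, 1L)                   # uncompressed
  entry(262L, 3L, 1L, 2L)                   # Photometric = RGB
  entry(273L, 4L, 1L, data_off)
  entry(277L, 3L, 1L, 3L)                   # SamplesPerPixel
  entry(278L, 4L, 1L, h)
  entry(279L, 4L, 1L, h * w * 3L * bytes_px)
  entry(284L, 3L, 1L, 1L)                   # chunky
  writeBin(0L, con, size = 4L, endian = "little")
  writeBin(rep(as.integer(bits), 3L), con, size = 2L, endian = "little")
  # interleave RGB, row-major
  v <- integer(h * w * 3L)
  for (s in 1:3) v[seq(s, length(v), by = 3L)] <- as.integer(t(a[, , s]))
  if (bits == 16L) v <- ifelse(v > 32767L, v - 65536L, v)
  writeBin(v, con, size = bytes_px, endian = "little")
  invisible(path)
}

read_tiff <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 8L) stop("not a TIFF file: ", path)
  bo <- rawToChar(raw[1:2])
  endian <- if (bo == "II") "little" else if (bo == "MM") "big" else
    stop("not a TIFF file: ", path)
  u <- function(off, size, n = 1L, signed = FALSE) {
    # read n unsigned ints of `size` bytes at 0-based offset `off`
    readBin(raw[(off + 1L):(off + n * size)], "integer", n = n, size = size,
            signed = if (size >= 4L) TRUE else signed, endian = endian)
  }
  u1 <- function(off, n = 1L) as.integer(raw[(off + 1L):(off + n)])
  magic <- u(2L, 2L)
  if (magic != 42L) stop("not a TIFF file: ", path)
  ifd <- u(4L, 4L)
  nent <- u(ifd, 2L)
  tags <- list()
  type_size <- c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L, 4L, 8L)
  for (i in seq_len(nent)) {
    e <- ifd + 2L + (i - 1L) * 12L
    tag <- u(e, 2L); type <- u(e + 2L, 2L); count <- u(e + 4L, 4L)
    ts <- type_size[type]
    total <- ts * count
    voff <- if (total <= 4L) e + 8L else u(e + 8L, 4L)
    vals <- if (type %in% c(3L)) u(voff, 2L, count)
      else if (type %in% c(4L, 9L)) u(voff, 4L, count)
      else if (type %in% c(1L, 2L, 6L, 7L)) u1(voff, count)
      else NA
    tags[[as.character(tag)]] <- vals
  }
  g <- function(tag, default = NULL) tags[[as.character(tag)]] %||% default
  w <- g(256); h <- g(257)
  if (is.null(w) || is.null(h)) stop("TIFF missing dimensions: ", path)
  comp <- g(259, 1L)
  if (comp != 1L) stop("only uncompressed TIFF is supported: ", path)
  spp <- g(277, 1L)
  bits <- g(258, 8L)
  if (length(unique(bits)) != 1L) stop("mixed bit depths unsupported")
  bits <- bits[1]
  if (!bits %in% c(8L, 16L, 32L)) stop("unsupported TIFF bit depth ", bits)
  planar <- g(284, 1L)
  if (planar != 1L) stop("planar TIFF unsupported")
  offsets <- g(273); counts <- g(279)
  if (is.null(offsets)) stop("TIFF missing strip offsets")
  bytes_px <- bits %/% 8L
  npx <- as.numeric(w) * h * spp
  if (is.null(counts)) counts <- npx * bytes_px
  vals <- integer(0)
  for (i in seq_along(offsets)) {
    n_i <- counts[i] %/% bytes_px
    if (bytes_px == 1L) {
      vals <- c(vals, u1(offsets[i], counts[i]))
    } else {
      vals <- c(vals, u(offsets[i], bytes_px, n_i))
    }
  }
  if (bytes_px == 2L) vals <- ifelse(vals < 0L, vals + 65536L, vals)
  if (length(vals) < npx) stop("truncated TIFF data: ", path)
  vals <- vals[seq_len(npx)]
  out <- if (spp == 1L) {
    matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  } else {
    a <- array(0L, dim = c(h, w, spp))
    for (s in seq_len(spp))
      a[, , s] <- matrix(vals[seq(s, npx, by = spp)], h, w, byrow = TRUE)
    a
  }
  attr(out, "bits") <- bits
  out
}

read_bmp <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 54L || rawToChar(raw[1:2]) != "BM")
    stop("not a BMP file: ", path)
  u <- function(off, size, signed = FALSE)
    readBin(raw[(off + 1L):(off + size)], "integer", size = size,
            signed = if (size >= 4L) TRUE else signed, endian = "little")
  data_off <- u(10L, 4L)
  hdr_size <- u(14L, 4L)
  if (hdr_size < 40L) stop("unsupported BMP header")
  w <- u(18L, 4L); h <- u(22L, 4L)
  bottom_up <- h > 0L; h <- abs(h)
  bpp <- u(28L, 2L)
  comp <- u(30L, 4L)
  if (comp != 0L || !bpp %in% c(24L, 32L))
    stop("only uncompressed 24/32-bit BMP supported: ", path)
  bytes <- bpp %/% 8L
  stride <- ((w * bytes + 3L) %/% 4L) * 4L
  a <- array(0L, dim = c(h, w, 3L))
  for (i in seq_len(h)) {
    roff <- data_off + (i - 1L) * stride
    rowv <- as.integer(raw[(roff + 1L):(roff + w * bytes)])
    m <- matrix(rowv, nrow = bytes)
    r_out <- if (bottom_up) h - i + 1L else i
    a[r_out, , 1L] <- m[3L, ]  # BGR order on disk
    a[r_out, , 2L] <- m[2L, ]
    a[r_out, , 3L] <- m[1L, ]
  }
  a
}
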