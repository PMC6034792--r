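# Minimal TIFF support: single-plane, uncompressed, grayscale, 8 or 16 bit.
# Device exports in this domain are plain rasters; no pre-installed package
# reads TIFF, so this covers exactly the baseline profile and refuses the rest.

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, samples = 277L,
               rows_per_strip = 278L, strip_byte_counts = 279L)

read_uint <- function(raw, offset, size, le) {
  b <- as.integer(raw[(offset + 1):(offset + size)])
  if (!le) b <- rev(b)
  sum(b * 256^(seq_len(size) - 1))
}

#' @noRd
read_tiff_gray <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8) stop("not a TIFF file: ", path)
  bom <- rawToChar(raw[1:2])
  le <- bom == "II"
  if (!le && bom != "MM") stop("not a TIFF file: ", path)
  if (read_uint(raw, 2, 2, le) != 42L) stop("not a TIFF file: ", path)
  ifd <- read_uint(raw, 4, 4, le)
  n_entries <- read_uint(raw, ifd, 2, le)
  tags <- list()
  for (k in seq_len(n_entries)) {
    ent <- ifd + 2 + (k - 1) * 12
    tag <- read_uint(raw, ent, 2, le)
    type <- read_uint(raw, ent + 2, 2, le)
    count <- read_uint(raw, ent + 4, 4, le)
    tsize <- c(1, 1, 2, 4, 8)[type]
    vals <- if (count * tsize <= 4) {
      vapply(seq_len(count), function(i)
        read_uint(raw, ent + 8 + (i - 1) * tsize, tsize, le), numeric(1))
    } else {
      off <- read_uint(raw, ent + 8, 4, le)
      vapply(seq_len(count), function(i)
        read_uint(raw, off + (i - 1) * tsize, tsize, le), numeric(1))
    }
    tags[[as.character(tag)]] <- vals
  }
  g <- function(id, default = NULL) {
    v <- tags[[as.character(id)]]
    if (is.null(v)) default else v
  }
  if (g(TIFF_TAGS["compression"], 1) != 1)
    stop("only uncompressed TIFF is supported")
  if (g(TIFF_TAGS["samples"], 1) != 1)
    stop("only single-sample (grayscale) TIFF is supported")
  bits <- g(TIFF_TAGS["bits"], 1)
  if (!bits %in% c(8, 16)) stop("only 8- or 16-bit TIFF is supported")
  w <- g(TIFF_TAGS["width"]); h <- g(TIFF_TAGS["length"])
  if (is.null(w) || is.null(h)) stop("TIFF missing image dimensions")
  offs <- g(TIFF_TAGS["strip_offsets"])
  counts <- g(TIFF_TAGS["strip_byte_counts"])
  data <- unlist(lapply(seq_along(offs), function(i)
    raw[(offs[i] + 1):(offs[i] + counts[i])]))
  npx <- w * h
  px <- if (bits == 8) {
    as.integer(data[seq_len(npx)])
  } else {
    b <- as.integer(data[seq_len(2 * npx)])
    if (le) b[seq(1, 2 * npx, 2)] + 256L * b[seq(2, 2 * npx, 2)]
    else    256L * b[seq(1, 2 * npx, 2)] + b[seq(2, 2 * npx, 2)]
  }
  list(pixels = matrix(px, nrow = h, ncol = w, byrow = TRUE), bits = bits)
}

#' @noRd
write_tiff_gray <- function(pixels, path, bits = 8) {
  stopifnot(bits %in% c(8, 16))
  h <- nrow(pixels); w <- ncol(pixels)
  px <- as.integer(round(t(pixels)))  # row-major
  if (any(px < 0) || any(px > 2^bits - 1)) stop("pixel values out of range")
  u <- function(x, size) { # little-endian raw
    b <- integer(size)
    for (i in seq_len(size)) { b[i] <- x %% 256; x <- x %/% 256 }
    as.raw(b)
  }
  data_off <- 8L
  nbytes <- w * h * (bits / 8)
  ifd_off <- data_off + nbytes
  entry <- function(tag, type, count, value)
    c(u(tag, 2), u(type, 2), u(count, 4), u(value, 4))
  entries <- list(
    entry(256, 3, 1, w), entry(257, 3, 1, h), entry(258, 3, 1, bits),
    entry(259, 3, 1, 1), entry(262, 3, 1, 1), entry(273, 4, 1, data_off),
    entry(277, 3, 1, 1), entry(278, 3, 1, h), entry(279, 4, 1, nbytes))
  payload <- if (bits == 8) as.raw(px) else {
    out <- raw(2 * length(px))
    out[seq(1, length(out), 2)] <- as.raw(px %% 256L)
    out[seq(2, length(out), 2)] <- as.raw(px %/% 256L)
    out
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), u(42, 2), u(data_off + nbytes, 4),
             payload, u(length(entries), 2), unlist(entries), u(0, 4)), con)
  invisible(path)
}
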