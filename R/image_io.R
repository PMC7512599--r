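# Raster input/output.  No TIFF/PNG bindings are assumed: the package
# carries its own readers/writers for plain PGM (P2 ASCII / P5 binary),
# minimal uncompressed grayscale TIFF (8/16-bit, little- or big-endian
# on read, little-endian single-strip on write) and headerless CSV
# frames.

# ---------------------------------------------------------------- PGM --

# tokenize a PNM header from raw bytes, honoring '#' comments
.pnm_tokens <- function(raw, ntok) {
  toks <- character(0)
  i <- 1L
  n <- length(raw)
  ws <- as.raw(c(0x20, 0x09, 0x0a, 0x0d, 0x0b, 0x0c))
  while (length(toks) < ntok && i <= n) {
    b <- raw[i]
    if (b == as.raw(0x23)) {                       # '#': skip to end of line
      while (i <= n && raw[i] != as.raw(0x0a)) i <- i + 1L
    } else if (b %in% ws) {
      i <- i + 1L
    } else {
      j <- i
      while (j <= n && !(raw[j] %in% ws) && raw[j] != as.raw(0x23)) j <- j + 1L
      toks <- c(toks, rawToChar(raw[i:(j - 1L)]))
      i <- j
    }
  }
  if (length(toks) < ntok) stop("truncated PNM header")
  list(tokens = toks, pos = i)
}

#' Read / write PGM (portable graymap) images
#'
#' Supports the ASCII `P2` and binary `P5` variants with maxval up to
#' 65535 (two-byte big-endian samples, per the PNM convention).
#'
#' @param path file path.
#' @param frame integer matrix of non-negative intensities.
#' @param maxval maximum sample value declared in the header; defaults to
#'   255 or 65535 depending on the frame's range.
#' @param ascii write `P2` (TRUE, default) or binary `P5`.
#' @return `read_pgm`: an integer matrix with attribute `maxval`;
#'   `write_pgm`: `path`, invisibly.
#' @export
read_pgm <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  hd <- .pnm_tokens(raw, 4L)
  magic <- hd$tokens[1]
  w <- as.integer(hd$tokens[2])
  h <- as.integer(hd$tokens[3])
  maxval <- as.integer(hd$tokens[4])
  if (is.na(w) || is.na(h) || is.na(maxval) || w < 1 || h < 1) {
    stop("malformed PGM header")
  }
  if (magic == "P2") {
    body <- rawToChar(raw[hd$pos:length(raw)])
    vals <- scan(text = body, what = integer(), comment.char = "#",
                 quiet = TRUE, n = w * h)
  } else if (magic == "P5") {
    start <- hd$pos + 1L                  # single whitespace after maxval
    sz <- if (maxval > 255) 2L else 1L
    vals <- readBin(raw[start:length(raw)], "integer", n = w * h,
                    size = sz, signed = FALSE, endian = "big")
  } else {
    stop("not a PGM file (expected P2 or P5)")
  }
  if (length(vals) < w * h) stop("truncated PGM pixel data")
  m <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  attr(m, "maxval") <- maxval
  m
}

#' @rdname read_pgm
#' @export
write_pgm <- function(frame, path, maxval = NULL, ascii = TRUE) {
  frame <- as.matrix(frame)
  if (!.is_count_vector(as.vector(frame))) stop("frame must hold non-negative integers")
  if (is.null(maxval)) maxval <- if (max(frame) <= 255) 255L else 65535L
  if (max(frame) > maxval) stop("intensities exceed maxval")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(sprintf("%s\n%d %d\n%d\n", if (ascii) "P2" else "P5",
                             ncol(frame), nrow(frame), maxval)), con)
  if (ascii) {
    lines <- apply(frame, 1, paste, collapse = " ")
    writeBin(charToRaw(paste0(paste(lines, collapse = "\n"), "\n")), con)
  } else {
    vals <- as.integer(t(frame))
    writeBin(vals, con, size = if (maxval > 255) 2L else 1L, endian = "big")
  }
  invisible(path)
}

# --------------------------------------------------------------- TIFF --

.tiff_u <- function(raw, off, size, endian) {
  # size-4 values are read signed: R has no unsigned 32-bit type, and all
  # offsets/counts in files this reader targets stay below 2^31
  readBin(raw[(off + 1):(off + size)], "integer", n = 1L, size = size,
          signed = (size == 4L), endian = endian)
}

# values of one IFD entry (types SHORT=3 and LONG=4 supported)
.tiff_values <- function(raw, off, endian) {
  type <- .tiff_u(raw, off + 2, 2L, endian)
  count <- .tiff_u(raw, off + 4, 4L, endian)
  size <- switch(as.character(type), "3" = 2L, "4" = 4L,
                 stop("unsupported TIFF field type ", type))
  src <- if (count * size <= 4L) off + 8 else .tiff_u(raw, off + 8, 4L, endian)
  vapply(seq_len(count) - 1L,
         function(i) .tiff_u(raw, src + i * size, size, endian), numeric(1))
}

#' Read / write minimal uncompressed grayscale TIFF stacks
#'
#' `read_tiff` parses uncompressed single-sample (grayscale, photometric
#' BlackIsZero) baseline TIFF files with 8- or 16-bit samples, both byte
#' orders, multiple pages and multiple strips.  `write_tiff` emits a
#' little-endian, single-strip-per-page stack (one page per frame), with
#' 8-bit samples when the sequence depth is 8 and 16-bit otherwise
#' (12-bit data travels in 16-bit containers, the usual convention).
#'
#' @param path file path.
#' @param seq a [frame_sequence()], a list of integer matrices, or one
#'   matrix.
#' @return `read_tiff`: a list of integer matrices with attribute
#'   `bits_per_sample`; `write_tiff`: `path`, invisibly.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  magic <- rawToChar(raw[1:2])
  endian <- if (magic == "II") "little" else if (magic == "MM") "big" else
    stop("not a TIFF file")
  if (.tiff_u(raw, 2, 2L, endian) != 42L) stop("not a TIFF file")
  off <- .tiff_u(raw, 4, 4L, endian)
  frames <- list()
  bits_seen <- integer(0)
  while (off != 0) {
    nent <- .tiff_u(raw, off, 2L, endian)
    tags <- list()
    for (e in seq_len(nent)) {
      eoff <- off + 2 + (e - 1L) * 12L
      tag <- .tiff_u(raw, eoff, 2L, endian)
      if (tag %in% c(256, 257, 258, 259, 262, 273, 277, 278, 279, 339)) {
        tags[[as.character(tag)]] <- .tiff_values(raw, eoff, endian)
      }
    }
    need <- c("256", "257", "273", "279")
    if (!all(need %in% names(tags))) stop("TIFF page misses required tags")
    w <- tags[["256"]]; h <- tags[["257"]]
    bits <- if (is.null(tags[["258"]])) 1L else tags[["258"]][1]
    comp <- if (is.null(tags[["259"]])) 1L else tags[["259"]]
    spp <- if (is.null(tags[["277"]])) 1L else tags[["277"]]
    sfmt <- if (is.null(tags[["339"]])) 1L else tags[["339"]][1]
    if (comp != 1L) stop("only uncompressed TIFF is supported")
    if (spp != 1L) stop("only single-sample (grayscale) TIFF is supported")
    if (sfmt != 1L) stop("only unsigned-integer TIFF samples are supported")
    if (!bits %in% c(8, 16)) stop("only 8- and 16-bit TIFF samples are supported")
    sz <- bits %/% 8L
    vals <- integer(0)
    for (s in seq_along(tags[["273"]])) {
      so <- tags[["273"]][s]
      nb <- tags[["279"]][s]
      vals <- c(vals, readBin(raw[(so + 1):(so + nb)], "integer",
                              n = nb %/% sz, size = sz, signed = FALSE,
                              endian = endian))
    }
    if (length(vals) != w * h) stop("TIFF strip data does not match dimensions")
    frames[[length(frames) + 1L]] <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
    bits_seen <- c(bits_seen, as.integer(bits))
    off <- .tiff_u(raw, off + 2 + nent * 12L, 4L, endian)
  }
  if (length(unique(bits_seen)) > 1L) stop("mixed sample depths within one TIFF")
  attr(frames, "bits_per_sample") <- bits_seen[1]
  frames
}

#' @rdname read_tiff
#' @export
write_tiff <- function(seq, path) {
  if (inherits(seq, "frame_sequence")) {
    frames <- seq$frames
    bits <- if (seq$bit_depth <= 8L) 8L else 16L
  } else {
    frames <- if (is.matrix(seq)) list(seq) else seq
    bits <- if (max(vapply(frames, max, numeric(1))) <= 255) 8L else 16L
  }
  sz <- bits %/% 8L
  npage <- length(frames)
  sizes <- vapply(frames, function(f) length(f) * sz, numeric(1))
  padded <- sizes + sizes %% 2                      # keep offsets even
  data_off <- 8 + cumsum(c(0, padded[-npage]))
  ifd_len <- 2 + 9 * 12 + 4
  ifd_off <- 8 + sum(padded) + (seq_len(npage) - 1L) * ifd_len
  con <- file(path, "wb")
  on.exit(close(con))
  u16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  writeBin(charToRaw("II"), con); u16(42L); u32(ifd_off[1])
  for (i in seq_len(npage)) {
    writeBin(as.integer(t(frames[[i]])), con, size = sz, endian = "little")
    if (padded[i] > sizes[i]) writeBin(as.raw(0), con)
  }
  entry <- function(tag, type, value) {            # count-1 entry, inline value
    u16(tag); u16(type); u32(1L)
    if (type == 3L) { u16(value); u16(0L) } else u32(value)
  }
  for (i in seq_len(npage)) {
    f <- frames[[i]]
    u16(9L)
    entry(256L, 4L, ncol(f))                       # ImageWidth
    entry(257L, 4L, nrow(f))                       # ImageLength
    entry(258L, 3L, bits)                          # BitsPerSample
    entry(259L, 3L, 1L)                            # Compression: none
    entry(262L, 3L, 1L)                            # Photometric: BlackIsZero
    entry(273L, 4L, data_off[i])                   # StripOffsets
    entry(277L, 3L, 1L)                            # SamplesPerPixel
    entry(278L, 4L, nrow(f))                       # RowsPerStrip
    entry(279L, 4L, sizes[i])                      # StripByteCounts
    u32(if (i < npage) ifd_off[i + 1] else 0L)
  }
  invisible(path)
}

# ----------------------------------------------------- sequence-level --

.read_one_raster <- function(file) {
  ext <- tolower(tools::file_ext(file))
  if (ext %in% c("pgm", "pnm")) {
    f <- read_pgm(file)
    container <- if (attr(f, "maxval") > 255) 16L else 8L
    attr(f, "maxval") <- NULL
    list(frames = list(f), container = container)
  } else if (ext %in% c("tif", "tiff")) {
    fr <- read_tiff(file)
    list(frames = fr, container = attr(fr, "bits_per_sample"))
  } else if (ext == "csv") {
    m <- as.matrix(utils::read.csv(file, header = FALSE))
    dimnames(m) <- NULL
    list(frames = list(m), container = if (max(m) > 255) 16L else 8L)
  } else {
    stop(sprintf("unreadable frame file (unknown format): %s", file))
  }
}

#' Read a frame sequence from files
#'
#' `path` may be a single file (multi-page TIFF pages become frames, in
#' page order), a directory, or a glob pattern; multiple files are
#' ordered lexicographically, which is taken as the time/z order.
#' Supported formats: PGM (P2/P5), uncompressed grayscale TIFF, and
#' headerless CSV.  All frames must agree in shape and container depth
#' (an 8-bit file mixed with 16-bit containers is an error naming the
#' offending file).  12-bit data in 16-bit containers is detected by the
#' max-value heuristic (maximum <= 4095) unless `bit_depth` overrides it.
#'
#' @param path file, directory or glob.
#' @param bit_depth optional explicit depth (8, 12 or 16).
#' @return a [frame_sequence()].
#' @export
read_sequence <- function(path, bit_depth = NULL) {
  files <- if (length(path) == 1L && dir.exists(path)) {
    list.files(path, full.names = TRUE)
  } else if (length(path) == 1L && grepl("[*?[]", path)) {
    Sys.glob(path)
  } else {
    path
  }
  files <- sort(files)
  if (length(files) < 1L) stop("no readable frames found")
  frames <- list()
  container <- NULL
  for (f in files) {
    r <- .read_one_raster(f)
    if (is.null(container)) {
      container <- r$container
    } else if (r$container != container) {
      stop(sprintf("mixed container bit depths: %s is %d-bit, expected %d-bit",
                   f, r$container, container))
    }
    for (fr in r$frames) {
      if (length(frames) > 0L && !identical(dim(fr), dim(frames[[1]]))) {
        stop(sprintf("frame shape mismatch in %s", f))
      }
      frames[[length(frames) + 1L]] <- fr
    }
  }
  if (is.null(bit_depth)) {
    maxv <- max(vapply(frames, max, numeric(1)))
    bit_depth <- if (container == 8L) 8L else if (maxv <= 4095) 12L else 16L
  }
  frame_sequence(frames, bit_depth = bit_depth)
}

#' Write a frame sequence
#'
#' `format = "tiff"` writes one multi-page TIFF at `path`; `"pgm"` and
#' `"csv"` write one file per frame (`frame_0001.pgm`, ...) into the
#' directory `path`, created if needed.
#'
#' @param seq a [frame_sequence()].
#' @param path output file (tiff) or directory (pgm/csv).
#' @param format `"tiff"`, `"pgm"` or `"csv"`.
#' @param ascii for PGM: ASCII `P2` (default) or binary `P5`.
#' @return `path`, invisibly.
#' @export
write_sequence <- function(seq, path, format = c("tiff", "pgm", "csv"),
                           ascii = TRUE) {
  stopifnot(inherits(seq, "frame_sequence"))
  format <- match.arg(format)
  if (format == "tiff") return(write_tiff(seq, path))
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  maxval <- if (seq$bit_depth <= 8L) 255L else 65535L
  for (i in seq_along(seq$frames)) {
    f <- file.path(path, sprintf("frame_%04d.%s", i,
                                 if (format == "pgm") "pgm" else "csv"))
    if (format == "pgm") {
      write_pgm(seq$frames[[i]], f, maxval = maxval, ascii = ascii)
    } else {
      utils::write.table(seq$frames[[i]], f, sep = ",", row.names = FALSE,
                         col.names = FALSE)
    }
  }
  invisible(path)
}
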