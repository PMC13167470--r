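# Baseline TIFF I/O: uncompressed, grayscale, little-endian, one page per
# plane. Covers uint8 / uint16 / float32, which is what microscopy
# pipelines exchange. No pre-installed R package provides TIFF in this
# stack, so the subset needed here is implemented directly; multi-channel
# arrays use the (C,[Z,]Y,X) axis convention recorded in the
# ImageDescription tag as JSON.

.TIFF_TYPES <- list(uint8 = list(bits = 8L, fmt = 1L, size = 1L),
                    uint16 = list(bits = 16L, fmt = 1L, size = 2L),
                    float32 = list(bits = 32L, fmt = 3L, size = 4L))

.tiff_tag <- function(id, type, count, value) {
  # returns raw(12); value must already fit in 4 bytes (or be an offset)
  v <- raw(4L)
  b <- writeBin(as.integer(value), raw(), size = if (type == 3L) 2L else 4L,
                endian = "little")
  v[seq_along(b)] <- b
  c(writeBin(as.integer(id), raw(), size = 2L, endian = "little"),
    writeBin(as.integer(type), raw(), size = 2L, endian = "little"),
    writeBin(as.integer(count), raw(), size = 4L, endian = "little"),
    v)
}

#' Write a multi-channel image as a multi-page TIFF
#'
#' Planes are written in `C` (then `Z`) order, one grayscale page each,
#' uncompressed little-endian. The axis string and dtype are stored as
#' JSON in the first page's ImageDescription, so [read_image()] restores
#' the array shape and metadata exactly.
#'
#' @param path output file
#' @param data matrix `(Y, X)` or array `(C, Y, X)` / `(C, Z, Y, X)`
#' @param dtype `"uint8"`, `"uint16"` or `"float32"`
#' @param axes axis string; inferred from the shape when `NULL`
#' @return `path`, invisibly
#' @export
write_image <- function(path, data, dtype = "float32", axes = NULL) {
  if (!dtype %in% names(.TIFF_TYPES))
    stop("write_image: unsupported dtype '", dtype, "'")
  tt <- .TIFF_TYPES[[dtype]]
  if (is.matrix(data)) data <- array(data, c(1L, dim(data)))
  nd <- length(dim(data))
  if (!nd %in% c(3L, 4L))
    stop("write_image: data must have axes (C,Y,X) or (C,Z,Y,X)")
  if (is.null(axes)) axes <- if (nd == 3L) "CYX" else "CZYX"
  d <- dim(data)
  H <- d[nd - 1L]; W <- d[nd]
  # pages ordered channel-major: page (c-1)*Z + z
  planes <- if (nd == 3L) {
    lapply(seq_len(d[1L]), function(c) matrix(data[c, , ], H, W))
  } else {
    unlist(lapply(seq_len(d[1L]), function(c)
      lapply(seq_len(d[2L]), function(z) matrix(data[c, z, , ], H, W))),
      recursive = FALSE)
  }
  n_pages <- length(planes)
  if (dtype != "float32") {
    maxv <- if (dtype == "uint8") 255 else 65535
    rngok <- vapply(planes, function(m)
      all(m >= 0) && all(m <= maxv) && all(m == round(m)), TRUE)
    if (!all(rngok))
      stop("write_image: data out of range for dtype '", dtype, "'")
  }
  desc <- jsonlite::toJSON(list(axes = axes, dtype = dtype,
                                shape = as.integer(d)), auto_unbox = TRUE)
  desc_raw <- c(charToRaw(as.character(desc)), as.raw(0L))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), as.raw(c(42L, 0L))), con)
  pos <- 8L  # next free offset; IFD offset of first page goes here
  # plan layout per page: [pixel data][description (page 1)][IFD]
  strip_len <- H * W * tt$size
  ifd_entry_counts <- integer(n_pages)
  offsets <- list()
  for (p in seq_len(n_pages)) {
    n_tags <- if (p == 1L) 11L else 10L
    strip_off <- pos
    desc_off <- strip_off + strip_len
    ifd_off <- desc_off + if (p == 1L) length(desc_raw) else 0L
    offsets[[p]] <- list(strip = strip_off, desc = desc_off, ifd = ifd_off,
                         n_tags = n_tags)
    pos <- ifd_off + 2L + n_tags * 12L + 4L
  }
  writeBin(writeBin(offsets[[1L]]$ifd, raw(), size = 4L, endian = "little"),
           con)
  for (p in seq_len(n_pages)) {
    o <- offsets[[p]]
    # pixel data, row-major
    vals <- as.numeric(t(planes[[p]]))
    if (dtype == "float32") {
      writeBin(vals, con, size = 4L, endian = "little")
    } else {
      writeBin(as.integer(vals), con, size = tt$size, endian = "little")
    }
    if (p == 1L) writeBin(desc_raw, con)
    tags <- list(
      .tiff_tag(256L, 4L, 1L, W),
      .tiff_tag(257L, 4L, 1L, H),
      .tiff_tag(258L, 3L, 1L, tt$bits),
      .tiff_tag(259L, 3L, 1L, 1L),
      .tiff_tag(262L, 3L, 1L, 1L))
    if (p == 1L)
      tags <- c(tags, list(.tiff_tag(270L, 2L, length(desc_raw), o$desc)))
    tags <- c(tags, list(
      .tiff_tag(273L, 4L, 1L, o$strip),
      .tiff_tag(277L, 3L, 1L, 1L),
      .tiff_tag(278L, 4L, 1L, H),
      .tiff_tag(279L, 4L, 1L, strip_len),
      .tiff_tag(339L, 3L, 1L, tt$fmt)))
    writeBin(writeBin(o$n_tags, raw(), size = 2L, endian = "little"), con)
    for (tg in tags) writeBin(tg, con)
    nxt <- if (p < n_pages) offsets[[p + 1L]]$ifd else 0L
    writeBin(writeBin(nxt, raw(), size = 4L, endian = "little"), con)
  }
  invisible(path)
}

.rd_int <- function(raw_vec, off, size, signed = FALSE) {
  # read little-endian unsigned integer at 1-based offset
  b <- as.integer(raw_vec[off:(off + size - 1L)])
  sum(b * 256^(seq_len(size) - 1L))
}

#' Read a TIFF written by [write_image()] (or any baseline uncompressed
#' grayscale little-endian TIFF)
#'
#' @param path input file
#' @return numeric array with attributes `axes` and `dtype`; shape
#'   restored from the embedded metadata when present, otherwise
#'   `(pages, Y, X)`
#' @export
read_image <- function(path) {
  raw_vec <- readBin(path, raw(), file.size(path))
  if (length(raw_vec) < 8L) stop("read_image: not a TIFF (file too short)")
  magic <- rawToChar(raw_vec[1:2])
  if (magic == "MM") stop("read_image: big-endian TIFF not supported")
  if (magic != "II" || .rd_int(raw_vec, 3L, 2L) != 42L)
    stop("read_image: not a TIFF file")
  ifd_off <- .rd_int(raw_vec, 5L, 4L)
  pages <- list()
  desc <- NULL
  while (ifd_off != 0L) {
    if (ifd_off + 1L > length(raw_vec)) stop("read_image: truncated IFD")
    n_tags <- .rd_int(raw_vec, ifd_off + 1L, 2L)
    tags <- list()
    for (i in seq_len(n_tags)) {
      base <- ifd_off + 2L + (i - 1L) * 12L + 1L
      id <- .rd_int(raw_vec, base, 2L)
      type <- .rd_int(raw_vec, base + 2L, 2L)
      count <- .rd_int(raw_vec, base + 4L, 4L)
      vsize <- c(1L, 1L, 2L, 4L, 8L)[min(type, 5L)]
      val <- if (vsize * count <= 4L) {
        vapply(seq_len(count), function(j)
          .rd_int(raw_vec, base + 8L + (j - 1L) * vsize, vsize), 0)
      } else {
        off <- .rd_int(raw_vec, base + 8L, 4L)
        if (id == 270L) {
          rawToChar(raw_vec[(off + 1L):(off + count - 1L)])
        } else {
          vapply(seq_len(count), function(j)
            .rd_int(raw_vec, off + 1L + (j - 1L) * vsize, vsize), 0)
        }
      }
      tags[[as.character(id)]] <- val
    }
    gt <- function(id, default = NULL) tags[[as.character(id)]] %||% default
    W <- gt(256L); H <- gt(257L)
    if (is.null(W) || is.null(H)) stop("read_image: missing dimensions")
    if (gt(259L, 1L) != 1L) stop("read_image: compressed TIFF not supported")
    if (gt(277L, 1L) != 1L)
      stop("read_image: only single-sample (grayscale) TIFF supported")
    bits <- gt(258L, 8L); fmt <- gt(339L, 1L)
    dtype <- if (fmt == 3L && bits == 32L) "float32"
             else if (fmt %in% c(1L, 4L) && bits == 16L) "uint16"
             else if (fmt %in% c(1L, 4L) && bits == 8L) "uint8"
             else stop("read_image: unsupported sample format (bits=", bits,
                       ", format=", fmt, ")")
    sz <- .TIFF_TYPES[[dtype]]$size
    sofs <- gt(273L); scnt <- gt(279L, H * W * sz)
    if (is.null(sofs)) stop("read_image: missing strip offsets")
    vals <- numeric(0)
    for (s in seq_along(sofs)) {
      o <- sofs[s]; n <- scnt[min(s, length(scnt))] %/% sz
      if (o + n * sz > length(raw_vec)) stop("read_image: truncated strips")
      chunk <- raw_vec[(o + 1L):(o + n * sz)]
      v <- if (dtype == "float32")
        readBin(chunk, numeric(), n, size = 4L, endian = "little")
      else readBin(chunk, integer(), n, size = sz, endian = "little",
                   signed = FALSE)
      vals <- c(vals, v)
    }
    if (length(vals) != H * W) stop("read_image: pixel count mismatch")
    pages[[length(pages) + 1L]] <- t(matrix(vals, W, H))  # stored row-major
    if (!is.null(gt(270L))) desc <- gt(270L)
    ifd_off <- .rd_int(raw_vec, ifd_off + 2L + n_tags * 12L + 1L, 4L)
    if (length(pages) > 4096L) stop("read_image: IFD chain too long")
  }
  H <- nrow(pages[[1L]]); W <- ncol(pages[[1L]])
  arr <- array(0, c(length(pages), H, W))
  for (p in seq_along(pages)) arr[p, , ] <- pages[[p]]
  axes <- "CYX"
  dtype_out <- NULL
  if (!is.null(desc)) {
    meta <- tryCatch(jsonlite::fromJSON(desc), error = function(e) NULL)
    if (!is.null(meta$shape) && length(meta$shape) %in% c(3L, 4L) &&
        prod(meta$shape) == length(arr)) {
      nd <- length(meta$shape)
      arr <- array(0, meta$shape)
      for (p in seq_along(pages)) {
        if (nd == 3L) arr[p, , ] <- pages[[p]]
        else {
          Z <- meta$shape[2L]
          ci <- (p - 1L) %/% Z + 1L
          zi <- (p - 1L) %% Z + 1L
          arr[ci, zi, , ] <- pages[[p]]
        }
      }
      axes <- meta$axes
      dtype_out <- meta$dtype
    }
  }
  attr(arr, "axes") <- axes
  attr(arr, "dtype") <- dtype_out %||% "unknown"
  arr
}
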