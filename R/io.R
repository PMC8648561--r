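# Volume I/O: multi-page TIFF (minimal baseline codec, uncompressed,
# little-endian) and HDF5 (via rhdf5). Grey-level scale and voxel size travel
# in a JSON sidecar next to TIFF stacks (TIFF tags are dialect-prone); HDF5
# carries them as attributes.

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(vol, path) {
  meta <- list(voxel_size_um = vol$voxel_size, origin_um = vol$origin,
               dtype_tag = vol$dtype_tag, scale = vol$scale)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
}

# --- minimal TIFF writer -----------------------------------------------------
# Baseline TIFF 6.0, little-endian, one strip per page, uncompressed.
# float32 (SampleFormat 3) or uint16 (SampleFormat 1), greyscale.

tiff_write_pages <- function(path, pages, bits, sample_format) {
  n <- length(pages)
  bytes_pp <- as.integer(bits %/% 8L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  # layout: [header 8][page1 data][page1 IFD][page2 data][page2 IFD]...
  page_bytes <- vapply(pages, function(p)
    as.integer(nrow(p)) * as.integer(ncol(p)) * bytes_pp, integer(1))
  n_entries <- 9L
  ifd_bytes <- 2L + n_entries * 12L + 4L
  # offset of each page's data block
  data_offs <- 8L + cumsum(c(0L, (page_bytes + ifd_bytes)[-n]))
  ifd_offs <- data_offs + page_bytes
  writeBin(as.integer(ifd_offs[1]), con, size = 4, endian = "little")
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) {  # SHORT: left-justified in 4-byte slot
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  for (p in seq_len(n)) {
    pg <- pages[[p]]
    w <- ncol(pg); h <- nrow(pg)
    # row-major pixel order: x fastest within a row
    v <- as.vector(t(pg))
    if (sample_format == 3L) {
      writeBin(v, con, size = 4, endian = "little")
    } else {
      v <- as.integer(round(v))
      # writeBin has no uint16; pack via raw
      r <- raw(length(v) * 2L)
      r[seq(1L, length(r), 2L)] <- as.raw(v %% 256L)
      r[seq(2L, length(r), 2L)] <- as.raw(v %/% 256L)
      writeBin(r, con)
    }
    next_ifd <- if (p < n) as.integer(ifd_offs[p] + ifd_bytes +
                                        page_bytes[p + 1L]) else 0L
    writeBin(n_entries, con, size = 2, endian = "little")
    entry(256L, 4L, 1L, w)                 # ImageWidth
    entry(257L, 4L, 1L, h)                 # ImageLength
    entry(258L, 3L, 1L, bits)              # BitsPerSample
    entry(259L, 3L, 1L, 1L)                # Compression: none
    entry(262L, 3L, 1L, 1L)                # Photometric: BlackIsZero
    entry(273L, 4L, 1L, data_offs[p])      # StripOffsets
    entry(278L, 4L, 1L, h)                 # RowsPerStrip
    entry(279L, 4L, 1L, page_bytes[p])     # StripByteCounts
    entry(339L, 3L, 1L, sample_format)     # SampleFormat
    writeBin(next_ifd, con, size = 4, endian = "little")
  }
  invisible(NULL)
}

tiff_read_pages <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (rawToChar(raw[1:2]) != "II")
    stop("only little-endian TIFF is supported", call. = FALSE)
  u16 <- function(i) as.integer(raw[i]) + 256L * as.integer(raw[i + 1L])
  u32 <- function(i) as.integer(raw[i]) + 256 * as.integer(raw[i + 1L]) +
    65536 * as.integer(raw[i + 2L]) + 16777216 * as.integer(raw[i + 3L])
  stopifnot(u16(3L) == 42L)
  ifd <- u32(5L)
  pages <- list(); meta <- NULL
  while (ifd != 0) {
    ne <- u16(ifd + 1L)
    tags <- list()
    for (e in seq_len(ne)) {
      base <- ifd + 2L + (e - 1L) * 12L + 1L
      tag <- u16(base); type <- u16(base + 2L)
      val <- if (type == 3L) u16(base + 8L) else u32(base + 8L)
      tags[[as.character(tag)]] <- val
    }
    w <- tags[["256"]]; h <- tags[["257"]]
    bits <- tags[["258"]]; comp <- tags[["259"]]
    off <- tags[["273"]]; nbytes <- tags[["279"]]
    sf <- if (!is.null(tags[["339"]])) tags[["339"]] else 1L
    if (comp != 1L) stop("compressed TIFF not supported", call. = FALSE)
    pm <- list(w = w, h = h, bits = bits, sf = sf)
    if (is.null(meta)) meta <- pm
    if (!identical(meta, pm))
      stop("TIFF pages differ in shape or sample format", call. = FALSE)
    bytes <- raw[(off + 1L):(off + nbytes)]
    if (sf == 3L && bits == 32L) {
      v <- readBin(bytes, "numeric", n = w * h, size = 4, endian = "little")
    } else if (sf == 1L && bits == 16L) {
      lo <- as.integer(bytes[seq(1L, length(bytes), 2L)])
      hi <- as.integer(bytes[seq(2L, length(bytes), 2L)])
      v <- lo + 256 * hi
    } else {
      stop("unsupported TIFF sample layout (need float32 or uint16)",
           call. = FALSE)
    }
    pages[[length(pages) + 1L]] <- t(matrix(v, nrow = w, ncol = h))
    ifd <- u32(ifd + 2L + ne * 12L + 1L)
  }
  list(pages = pages, bits = meta$bits, sf = meta$sf)
}

# --- public API --------------------------------------------------------------

#' Write a volume to disk
#'
#' `tiff_stack` writes one multi-page uncompressed little-endian TIFF with a
#' JSON sidecar (`<path>.json`) holding voxel size, origin, dtype and the
#' uint16 grey-level scale. `hdf5` writes group `/volume` with attributes
#' `voxel_size_um`, `origin_um`, `dtype_tag` and `scale` (requires the
#' `rhdf5` package). Both paths are lossless for float32 data and
#' deterministic given identical input.
#'
#' @param vol a [volume3d()].
#' @param path output file path.
#' @param format `"tiff_stack"` or `"hdf5"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = c("tiff_stack", "hdf5")) {
  format <- match.arg(format)
  stopifnot(inherits(vol, "volume3d"))
  if (vol$dtype_tag == "uint16") {
    if (any(!is.finite(vol$data)))
      stop("uint16 volumes must not contain NaN/Inf", call. = FALSE)
    if (any(vol$data < 0 | vol$data > 65535))
      stop("uint16 stored values must lie in [0, 65535]", call. = FALSE)
  }
  if (format == "tiff_stack") {
    d <- dim(vol$data)
    pages <- lapply(seq_len(d[3]), function(k) t(vol$data[, , k]))
    # pages as [row = y, col = x]
    if (vol$dtype_tag == "float32")
      tiff_write_pages(path, pages, 32L, 3L)
    else
      tiff_write_pages(path, pages, 16L, 1L)
    write_sidecar(vol, path)
  } else {
    if (!requireNamespace("rhdf5", quietly = TRUE))
      stop("hdf5 format requires the rhdf5 package", call. = FALSE)
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5createGroup(path, "volume")
    rhdf5::h5write(vol$data, path, "volume/data")
    fid <- rhdf5::H5Fopen(path)
    gid <- rhdf5::H5Gopen(fid, "volume")
    rhdf5::h5writeAttribute(vol$voxel_size, gid, "voxel_size_um")
    rhdf5::h5writeAttribute(vol$origin, gid, "origin_um")
    rhdf5::h5writeAttribute(vol$dtype_tag, gid, "dtype_tag")
    rhdf5::h5writeAttribute(vol$scale, gid, "scale")
    rhdf5::H5Gclose(gid); rhdf5::H5Fclose(fid)
  }
  invisible(path)
}

#' Read a volume from disk
#'
#' Counterpart of [write_volume()]. For TIFF stacks the voxel size is taken
#' from the JSON sidecar when present; otherwise `voxel_size` must be given
#' explicitly.
#'
#' @param path file path.
#' @param format `"tiff_stack"` or `"hdf5"`.
#' @param voxel_size voxel size in µm, required if no sidecar metadata exists.
#' @return a [volume3d()].
#' @export
read_volume <- function(path, format = c("tiff_stack", "hdf5"),
                        voxel_size = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "tiff_stack") {
    tf <- tiff_read_pages(path)
    d <- c(ncol(tf$pages[[1]]), nrow(tf$pages[[1]]), length(tf$pages))
    arr <- array(0, d)
    for (k in seq_len(d[3])) arr[, , k] <- t(tf$pages[[k]])
    meta <- NULL
    if (file.exists(sidecar_path(path)))
      meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
    vs <- if (!is.null(meta)) meta$voxel_size_um else voxel_size
    if (is.null(vs))
      stop("voxel size unknown: no sidecar, pass `voxel_size` explicitly",
           call. = FALSE)
    origin <- if (!is.null(meta)) meta$origin_um else c(0, 0, 0)
    dtype <- if (tf$sf == 3L) "float32" else "uint16"
    scale <- if (!is.null(meta) && !is.null(meta$scale)) meta$scale else c(0, 1)
    volume3d(arr, vs, origin, dtype, scale)
  } else {
    if (!requireNamespace("rhdf5", quietly = TRUE))
      stop("hdf5 format requires the rhdf5 package", call. = FALSE)
    arr <- rhdf5::h5read(path, "volume/data")
    at <- rhdf5::h5readAttributes(path, "volume")
    vs <- if (!is.null(at$voxel_size_um)) as.numeric(at$voxel_size_um)
          else voxel_size
    if (is.null(vs))
      stop("voxel size unknown: missing attribute, pass `voxel_size`",
           call. = FALSE)
    volume3d(arr, vs,
             if (!is.null(at$origin_um)) as.numeric(at$origin_um) else c(0, 0, 0),
             if (!is.null(at$dtype_tag)) at$dtype_tag else "float32",
             if (!is.null(at$scale)) as.numeric(at$scale) else c(0, 1))
  }
}
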