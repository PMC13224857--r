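# Minimal multi-page TIFF support for image stacks. No TIFF package is
# available in the target environment, so the package carries a small
# baseline codec: uncompressed, little-endian, 32-bit IEEE float,
# single-sample grayscale, one strip per page. This covers round-tripping
# the package's own stacks and reading stacks written the same way by
# common scientific writers (e.g. tifffile with default float output).

.TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
                photometric = 262L, strip_offsets = 273L, spp = 277L,
                rows_per_strip = 278L, strip_bytes = 279L,
                sample_format = 339L)

#' Write a 3D stack as a multi-page float TIFF
#'
#' Each z-plane becomes one grayscale 32-bit float page (uncompressed,
#' little-endian).
#'
#' @param stack 3D numeric array `(z, y, x)`.
#' @param path Output file.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(length(dim(stack)) == 3L)
  nz <- dim(stack)[1]; ny <- dim(stack)[2]; nx <- dim(stack)[3]
  page_bytes <- ny * nx * 4L
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2,
                             endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4,
                             endian = "little")
  writeBin(charToRaw("II"), con)
  w2(42L)
  data_start <- 8L
  ifd_start <- data_start + nz * page_bytes
  w4(ifd_start)  # first IFD comes after all pixel data
  for (z in seq_len(nz)) {
    plane <- t(stack[z, , ])  # row-major: y rows of x values
    writeBin(as.numeric(plane), con, size = 4, endian = "little")
  }
  n_entries <- 10L
  ifd_size <- 2L + n_entries * 12L + 4L
  entry <- function(tag, type, value) {  # type 3 = SHORT, 4 = LONG
    w2(tag); w2(type); w4(1L)
    if (type == 3L) { w2(value); w2(0L) } else w4(value)
  }
  for (z in seq_len(nz)) {
    w2(n_entries)
    entry(256L, 4L, nx)
    entry(257L, 4L, ny)
    entry(258L, 3L, 32L)
    entry(259L, 3L, 1L)              # no compression
    entry(262L, 3L, 1L)              # black-is-zero
    entry(273L, 4L, data_start + (z - 1L) * page_bytes)
    entry(277L, 3L, 1L)              # one sample per pixel
    entry(278L, 4L, ny)              # one strip per page
    entry(279L, 4L, page_bytes)
    entry(339L, 3L, 3L)              # IEEE float
    nxt <- if (z < nz) ifd_start + z * ifd_size else 0L
    w4(nxt)
  }
  invisible(path)
}

#' Read a multi-page float TIFF written by [write_stack_tiff()]
#'
#' Supports little-endian uncompressed 32-bit float grayscale pages with a
#' single strip (or contiguously stored strips).
#'
#' @param path TIFF file.
#' @return 3D numeric array `(z, y, x)`.
#' @export
read_stack_tiff <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.numeric(raw[off + 1:4]) * 256^(0:3))
  if (rawToChar(raw[1:2]) != "II" || u16(2) != 42L)
    stop("not a little-endian TIFF", call. = FALSE)
  ifd <- u32(4)
  planes <- list()
  while (ifd != 0) {
    n <- u16(ifd)
    tags <- list()
    for (e in seq_len(n)) {
      off <- ifd + 2 + (e - 1) * 12
      tag <- u16(off); type <- u16(off + 2); count <- u32(off + 4)
      val <- if (type == 3L) u16(off + 8) else u32(off + 8)
      if (count > 1L) val <- u32(off + 8)  # treat as offset; not needed here
      tags[[as.character(tag)]] <- val
    }
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    if (g(259L, 1L) != 1L) stop("compressed TIFF unsupported", call. = FALSE)
    if (g(258L, 32L) != 32L || g(339L, 3L) != 3L)
      stop("only 32-bit float TIFF supported", call. = FALSE)
    nx <- g(256L); ny <- g(257L)
    data_off <- g(273L)
    vals <- readBin(raw[(data_off + 1):(data_off + nx * ny * 4)],
                    "numeric", n = nx * ny, size = 4, endian = "little")
    planes[[length(planes) + 1L]] <- matrix(vals, ny, nx, byrow = TRUE)
    ifd <- u32(ifd + 2 + n * 12)
  }
  nz <- length(planes)
  out <- array(0, c(nz, nrow(planes[[1]]), ncol(planes[[1]])))
  for (z in seq_len(nz)) out[z, , ] <- planes[[z]]
  out
}
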