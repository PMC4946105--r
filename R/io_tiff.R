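# Minimal baseline TIFF codec: multi-page, 8-bit grayscale, uncompressed,
# little-endian, one strip per page. Pixel size is carried in the
# X/YResolution rationals (pixels per cm) and free-form metadata (JSON) in
# ImageDescription. This is deliberately the smallest interoperable subset -
# the offline toolchain has no TIFF package to lean on - and any file outside
# that subset is rejected with an explicit format error.

u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

ifd_entry <- function(tag, type, count, value) {
  # value: already-packed 4 raw bytes (offset or inline value)
  c(u16(tag), u16(type), u32(count), value)
}

#' Write a multi-page 8-bit grayscale TIFF
#'
#' @param pages A numeric matrix or list of matrices (values 0-255; rows = y).
#' @param path Output path.
#' @param pixel_size_um Pixel size (um/px), stored in the resolution tags.
#' @param description Character scalar or vector (recycled per page) stored
#'   in ImageDescription; use JSON for structured metadata such as exposure.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(pages, path, pixel_size_um = NA_real_, description = "") {
  if (is.matrix(pages)) pages <- list(pages)
  stopifnot(length(pages) >= 1L, all(vapply(pages, is.matrix, logical(1))))
  description <- rep_len(as.character(description), length(pages))
  ppcm <- if (is.finite(pixel_size_um)) 10000 / pixel_size_um else 1
  # rational approximation n/d for pixels-per-cm
  d <- 1000L
  n <- as.integer(round(ppcm * d))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(u16(42L), con)
  offset <- 8L
  ifd_off_pos <- 4L       # where the first-IFD pointer lives
  writeBin(u32(0L), con)  # first-IFD pointer, patched at the end
  page_ifd_offsets <- integer(length(pages))
  for (p in seq_along(pages)) {
    m <- pages[[p]]
    h <- nrow(m); w <- ncol(m)
    desc <- c(charToRaw(description[p]), as.raw(0))
    if (length(desc) %% 2 == 1) desc <- c(desc, as.raw(0))
    data_off <- offset
    nbytes <- w * h
    if (nbytes %% 2 == 1) nbytes_pad <- nbytes + 1 else nbytes_pad <- nbytes
    desc_off <- data_off + nbytes_pad
    res_off <- desc_off + length(desc)
    ifd_off <- res_off + 16L
    page_ifd_offsets[p] <- ifd_off
    # pixel data, row-major
    vals <- as.integer(round(t(m)))
    vals <- pmin(pmax(vals, 0L), 255L)
    writeBin(as.raw(vals), con)
    if (nbytes_pad > nbytes) writeBin(as.raw(0), con)
    writeBin(desc, con)
    writeBin(c(u32(n), u32(d), u32(n), u32(d)), con)  # X and Y resolution
    entries <- list(
      ifd_entry(256, 4, 1, u32(w)),
      ifd_entry(257, 4, 1, u32(h)),
      ifd_entry(258, 3, 1, c(u16(8L), u16(0L))),
      ifd_entry(259, 3, 1, c(u16(1L), u16(0L))),
      ifd_entry(262, 3, 1, c(u16(1L), u16(0L))),
      ifd_entry(270, 2, length(desc), u32(desc_off)),
      ifd_entry(273, 4, 1, u32(data_off)),
      ifd_entry(277, 3, 1, c(u16(1L), u16(0L))),
      ifd_entry(278, 4, 1, u32(h)),
      ifd_entry(279, 4, 1, u32(w * h)),
      ifd_entry(282, 5, 1, u32(res_off)),
      ifd_entry(283, 5, 1, u32(res_off + 8L)),
      ifd_entry(296, 3, 1, c(u16(3L), u16(0L))))
    writeBin(u16(length(entries)), con)
    for (e in entries) writeBin(e, con)
    ifd_size <- 2L + 12L * length(entries) + 4L
    next_ifd <- 0L
    # next page's IFD offset: its data starts right after this IFD
    if (p < length(pages)) {
      m2 <- pages[[p + 1]]
      nb2 <- nrow(m2) * ncol(m2); if (nb2 %% 2 == 1) nb2 <- nb2 + 1
      d2 <- c(charToRaw(description[p + 1]), as.raw(0))
      if (length(d2) %% 2 == 1) d2 <- c(d2, as.raw(0))
      next_data <- ifd_off + ifd_size
      next_ifd <- next_data + nb2 + length(d2) + 16L
    }
    writeBin(u32(next_ifd), con)
    offset <- ifd_off + ifd_size
  }
  # patch first IFD pointer
  seek(con, ifd_off_pos, rw = "write")
  writeBin(u32(page_ifd_offsets[1]), con)
  invisible(path)
}

read_u <- function(raw, at, size) {
  # read little-endian unsigned int of `size` bytes at 0-based offset `at`
  if (at + size > length(raw)) stop("truncated TIFF: unexpected end of file", call. = FALSE)
  sum(as.numeric(raw[(at + 1):(at + size)]) * 256^(0:(size - 1)))
}

#' Read a multi-page TIFF written by [write_tiff()]
#'
#' Supports the codec's subset: little-endian, uncompressed, 8-bit grayscale,
#' one strip per page. Anything else raises an explicit format error.
#'
#' @param path TIFF path.
#' @return List with `pages` (list of numeric matrices), `pixel_size_um`, and
#'   `descriptions` (character per page); the first description is also
#'   attached as attribute `description`.
#' @export
read_tiff <- function(path) {
  rawv <- readBin(path, "raw", n = file.info(path)$size)
  if (length(rawv) < 8) stop("truncated TIFF: file too short", call. = FALSE)
  if (rawToChar(rawv[1:2]) != "II" || read_u(rawv, 2, 2) != 42)
    stop("not a little-endian TIFF", call. = FALSE)
  ifd <- read_u(rawv, 4, 4)
  pages <- list(); descs <- character(); psz <- NA_real_
  while (ifd != 0) {
    nent <- read_u(rawv, ifd, 2)
    tags <- list()
    for (e in seq_len(nent)) {
      base <- ifd + 2 + (e - 1) * 12
      tag <- read_u(rawv, base, 2)
      type <- read_u(rawv, base + 2, 2)
      cnt <- read_u(rawv, base + 4, 4)
      val <- if (type == 3 && cnt == 1) read_u(rawv, base + 8, 2) else read_u(rawv, base + 8, 4)
      tags[[as.character(tag)]] <- list(type = type, count = cnt, value = val)
    }
    need <- function(t) {
      x <- tags[[as.character(t)]]
      if (is.null(x)) stop("TIFF missing required tag ", t, call. = FALSE)
      x
    }
    w <- need(256)$value; h <- need(257)$value
    if (need(258)$value != 8) stop("unsupported TIFF: not 8-bit", call. = FALSE)
    if (need(259)$value != 1) stop("unsupported TIFF: compressed", call. = FALSE)
    so <- need(273); sbc <- need(279)
    if (so$count != 1) stop("unsupported TIFF: multiple strips", call. = FALSE)
    if (sbc$value != w * h) stop("corrupt TIFF: strip byte count mismatch", call. = FALSE)
    if (so$value + w * h > length(rawv)) stop("truncated TIFF: pixel data missing", call. = FALSE)
    px <- as.numeric(rawv[(so$value + 1):(so$value + w * h)])
    pages[[length(pages) + 1]] <- matrix(px, nrow = h, ncol = w, byrow = TRUE)
    dsc <- tags[["270"]]
    descs <- c(descs, if (!is.null(dsc)) {
      s <- rawv[(dsc$value + 1):(dsc$value + dsc$count)]
      rawToChar(s[s != as.raw(0)])
    } else "")
    xr <- tags[["282"]]
    if (!is.null(xr) && is.na(psz)) {
      num <- read_u(rawv, xr$value, 4); den <- read_u(rawv, xr$value + 4, 4)
      if (num > 0) psz <- 10000 / (num / den)
    }
    ifd <- read_u(rawv, ifd + 2 + nent * 12, 4)
  }
  out <- list(pages = pages, pixel_size_um = psz, descriptions = descs)
  attr(out, "description") <- if (length(descs)) descs[1] else ""
  out
}
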