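#' A single 2-D intensity channel
#'
#' Light container for one co-registered channel of a multimodal
#' acquisition: a nonnegative, finite 2-D intensity grid, its channel
#' identity, and the pixel size (images are acquired at 1 x 1 um per pixel).
#'
#' @param pixels Numeric matrix of intensities, all finite and `>= 0`.
#' @param channel_id One of [channel_ids()].
#' @param pixel_size Pixel side, micrometres.
#' @return An object of class `channel_image`.
#' @export
channel_image <- function(pixels, channel_id, pixel_size = 1.0) {
  stopifnot(is.matrix(pixels))
  if (!all(is.finite(pixels))) abort("channel intensities must be finite")
  if (min(pixels) < 0) abort("channel intensities must be >= 0")
  channel_id <- match.arg(channel_id, channel_ids())
  structure(list(pixels = pixels, channel_id = channel_id,
                 pixel_size = pixel_size),
            class = "channel_image")
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> %s %dx%d px (%.3g um/px), range [%.4g, %.4g]\n",
              x$channel_id, nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' A co-registered multichannel stack
#'
#' @param channels List of [channel_image()]s sharing one pixel grid;
#'   channel ids must be unique.
#' @param sample_id Sample identifier.
#' @param genotype Genotype tag (e.g. `"WT"`, `"KO"`).
#' @param polarization Optional free-form polarization note.
#' @return An object of class `multimodal_stack`; channels are stored in
#'   canonical [channel_ids()] order and retrievable by id with `$channels`.
#' @export
multimodal_stack <- function(channels, sample_id = "sample",
                             genotype = NA_character_,
                             polarization = NA_character_) {
  stopifnot(length(channels) >= 1)
  ids <- vapply(channels, function(ch) ch$channel_id, character(1))
  if (anyDuplicated(ids)) abort("channel ids must be unique within a stack")
  dims <- vapply(channels, function(ch) dim(ch$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    abort("all channels in a stack must share the same shape")
  ord <- order(match(ids, channel_ids()))
  structure(list(channels = setNames(channels[ord], ids[ord]),
                 sample_id = sample_id, genotype = genotype,
                 polarization = polarization),
            class = "multimodal_stack")
}

#' @export
print.multimodal_stack <- function(x, ...) {
  d <- dim(x$channels[[1]]$pixels)
  cat(sprintf("<multimodal_stack> '%s' (%s): %d channel(s), %dx%d px\n",
              x$sample_id, x$genotype, length(x$channels), d[1], d[2]))
  cat(" ", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

## ---- minimal multipage TIFF writer -----------------------------------------
## Baseline little-endian TIFF, one strip per page, uncompressed, grayscale.
## Written by hand because the established R writer stores only [0,1]-scaled
## integer samples: it cannot emit IEEE-float sample format (needed for
## bit-exact float round trips) nor per-page ImageDescription tags.

tiff_dtype <- function(dtype) {
  switch(dtype,
         uint8 = list(bits = 8L, fmt = 1L, bytes = 1L),
         uint16 = list(bits = 16L, fmt = 1L, bytes = 2L),
         float32 = list(bits = 32L, fmt = 3L, bytes = 4L),
         abort("dtype must be one of uint8, uint16, float32"))
}

write_tiff_pages <- function(pages, descriptions, path, dtype) {
  dt <- tiff_dtype(dtype)
  n <- length(pages)
  # ASCII tag data is NUL-terminated on write (R strings cannot hold NUL)
  desc <- descriptions
  desc_len <- nchar(desc, type = "bytes") + 1L
  ntags <- 11L
  ifd_size <- 2L + 12L * ntags + 4L

  # lay out: header | per page (pixel data, description if >4 bytes, IFD)
  offs <- vector("list", n)
  pos <- 8L
  for (i in seq_len(n)) {
    npx <- length(pages[[i]])
    data_off <- pos
    pos <- pos + npx * dt$bytes
    if (pos %% 2L) pos <- pos + 1L
    desc_off <- if (desc_len[i] > 4L) pos else NA_integer_
    if (desc_len[i] > 4L) {
      pos <- pos + desc_len[i]
      if (pos %% 2L) pos <- pos + 1L
    }
    ifd_off <- pos
    pos <- pos + ifd_size
    offs[[i]] <- list(data = data_off, desc = desc_off, ifd = ifd_off,
                      nbytes = npx * dt$bytes)
  }

  con <- file(path, "wb")
  on.exit(close(con))
  wb <- function(x, size) writeBin(x, con, size = size, endian = "little")
  w16 <- function(x) wb(as.integer(ifelse(x > 32767, x - 65536, x)), 2L)
  w32 <- function(x) wb(as.integer(x), 4L)

  writeBin(charToRaw("II"), con); w16(42L); w32(offs[[1]]$ifd)
  for (i in seq_len(n)) {
    at <- seek(con)
    stopifnot(at == offs[[i]]$data)
    v <- as.vector(t(pages[[i]]))  # TIFF strips are row-major
    if (dtype == "uint8") {
      writeBin(as.raw(v), con)
    } else if (dtype == "uint16") {
      w16(v)
    } else {
      writeBin(as.numeric(v), con, size = 4L, endian = "little")
    }
    if (seek(con) %% 2L) writeBin(as.raw(0L), con)
    if (!is.na(offs[[i]]$desc)) {
      writeBin(c(charToRaw(desc[i]), as.raw(0L)), con)
      if (seek(con) %% 2L) writeBin(as.raw(0L), con)
    }
    stopifnot(seek(con) == offs[[i]]$ifd)

    entry <- function(tag, type, count, value) {
      w16(tag); w16(type); w32(count)
      if (type == 3L && count == 1L) { w16(value); w16(0L) } else w32(value)
    }
    w16(ntags)
    pg <- pages[[i]]
    entry(256L, 4L, 1L, ncol(pg))              # ImageWidth
    entry(257L, 4L, 1L, nrow(pg))              # ImageLength
    entry(258L, 3L, 1L, dt$bits)               # BitsPerSample
    entry(259L, 3L, 1L, 1L)                    # Compression: none
    entry(262L, 3L, 1L, 1L)                    # Photometric: black is zero
    if (is.na(offs[[i]]$desc)) {               # ImageDescription
      w16(270L); w16(2L); w32(desc_len[i])
      raw4 <- c(charToRaw(desc[i]),
                as.raw(rep(0L, 4L - desc_len[i] + 1L)))
      writeBin(raw4, con)
    } else {
      entry(270L, 2L, desc_len[i], offs[[i]]$desc)
    }
    entry(273L, 4L, 1L, offs[[i]]$data)        # StripOffsets
    entry(277L, 3L, 1L, 1L)                    # SamplesPerPixel
    entry(278L, 4L, 1L, nrow(pg))              # RowsPerStrip
    entry(279L, 4L, 1L, offs[[i]]$nbytes)      # StripByteCounts
    entry(339L, 3L, 1L, dt$fmt)                # SampleFormat
    w32(if (i < n) offs[[i + 1]]$ifd else 0L)  # next IFD
  }
  invisible(path)
}

# internal: undo readTIFF's [0,1] scaling for integer pages; float pages
# come back verbatim
decode_page <- function(pg) {
  fmt <- attr(pg, "sample.format") %||% "uint"
  bits <- attr(pg, "bits.per.sample") %||% 8L
  m <- if (length(dim(pg)) == 3L) pg[, , 1L] else pg
  m <- matrix(as.numeric(m), nrow = dim(pg)[1])
  if (identical(fmt, "float")) m else round(m * (2^bits - 1))
}

#' Write / read a multimodal stack as a multipage TIFF
#'
#' One grayscale page per channel in canonical [channel_ids()] order, channel
#' id in each page's ImageDescription tag, plus a sidecar YAML file
#' (`<path>.yml`) carrying sample metadata and pixel size. Round trips are
#' bit-exact: integer data is stored verbatim at the chosen bit depth and
#' `float32` data at IEEE single precision (doubles are quantized to float
#' once on first write; re-reading and re-writing is then an identity).
#'
#' @param stack A [multimodal_stack()].
#' @param path Output TIFF path.
#' @param dtype Storage type: `"float32"` (default), `"uint16"`, `"uint8"`.
#'   Integer types require integer-valued intensities within range.
#' @return `write_stack()` returns `path` invisibly; `read_stack()` the
#'   reconstructed [multimodal_stack()].
#' @export
write_stack <- function(stack, path, dtype = "float32") {
  stopifnot(inherits(stack, "multimodal_stack"))
  dt <- tiff_dtype(dtype)
  pages <- lapply(stack$channels, function(ch) ch$pixels)
  if (dt$fmt == 1L) {
    mx <- 2^dt$bits - 1
    ok <- vapply(pages, function(p) all(p == round(p) & p <= mx), logical(1))
    if (!all(ok))
      abort(sprintf("%s storage needs integer intensities in [0, %d]",
                    dtype, as.integer(mx)))
  }
  write_tiff_pages(pages, names(stack$channels), path, dtype)
  yaml::write_yaml(list(sample_id = stack$sample_id,
                        genotype = stack$genotype,
                        polarization = stack$polarization,
                        pixel_size = stack$channels[[1]]$pixel_size,
                        channels = names(stack$channels)),
                   stack_sidecar(path))
  invisible(path)
}

stack_sidecar <- function(path) paste0(path, ".yml")

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    abort("format error: TIFF pages have mismatched sizes")
  ids <- vapply(pages, function(p) {
    trimws(attr(p, "description") %||% "")
  }, character(1))
  if (!all(ids %in% channel_ids()))
    abort(paste0("format error: unknown channel tag(s): ",
                 toString(setdiff(ids, channel_ids()))))
  meta <- if (file.exists(stack_sidecar(path)))
    yaml::read_yaml(stack_sidecar(path)) else list()
  px <- meta$pixel_size %||% 1.0
  channels <- purrr::map2(pages, ids,
                          ~ channel_image(decode_page(.x), .y, px))
  multimodal_stack(channels,
                   sample_id = meta$sample_id %||% basename(path),
                   genotype = meta$genotype %||% NA_character_,
                   polarization = meta$polarization %||% NA_character_)
}

#' Write / read a region label map as an 8-bit TIFF
#'
#' Single-page 8-bit grayscale TIFF whose pixel values are the
#' [label_codes()] themselves.
#'
#' @param labels Integer matrix of [label_codes()] values.
#' @param path File path.
#' @return `write_label_map()` returns `path` invisibly; `read_label_map()`
#'   the integer label matrix (class `region_label_map`).
#' @export
write_label_map <- function(labels, path) {
  if (!all(labels %in% label_codes())) abort("labels contain unknown codes")
  write_tiff_pages(list(matrix(as.numeric(labels), nrow(labels))),
                   "region_label_map", path, "uint8")
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  pg <- tiff::readTIFF(path, info = TRUE)
  m <- matrix(as.integer(decode_page(pg)), nrow = dim(pg)[1])
  if (!all(m %in% label_codes()))
    abort("format error: file contains values outside the label code table")
  class(m) <- c("region_label_map", class(m))
  m
}

#' Export a multicolor composite of selected channels
#'
#' Min-max scales each selected channel to `[0, 1]`, tints it with its
#' assigned color, and blends the layers additively (clipped to the display
#' range) -- the standard multimodal overlay view. Purely a visualization:
#' stored data is never altered.
#'
#' @param stack A [multimodal_stack()].
#' @param color_map Named list/vector mapping channel ids to colors (any R
#'   color specification), e.g. `c(SHG_PAR = "blue", SRS_2850 = "magenta")`.
#' @param path Output PNG path.
#' @return The `height x width x 3` RGB array, invisibly.
#' @export
export_composite <- function(stack, color_map, path) {
  stopifnot(inherits(stack, "multimodal_stack"))
  if (length(color_map) < 1) abort("select at least one channel")
  ids <- names(color_map)
  missing_ids <- setdiff(ids, names(stack$channels))
  if (length(missing_ids))
    abort(paste0("stack has no channel(s): ", toString(missing_ids)))
  d <- dim(stack$channels[[1]]$pixels)
  rgb_img <- array(0, c(d[1], d[2], 3))
  for (id in ids) {
    px <- stack$channels[[id]]$pixels
    rng <- range(px)
    scaled <- if (rng[2] > rng[1]) (px - rng[1]) / (rng[2] - rng[1])
              else matrix(0, d[1], d[2])
    tint <- grDevices::col2rgb(color_map[[id]])[, 1] / 255
    for (k in 1:3) rgb_img[, , k] <- rgb_img[, , k] + scaled * tint[k]
  }
  rgb_img[rgb_img > 1] <- 1
  png::writePNG(rgb_img, path)
  invisible(rgb_img)
}
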