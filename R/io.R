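#' Read a grayscale TIFF image or stack
#'
#' Integer samples are returned exactly (no rescaling to [0, 1]); 32-bit
#' float samples are returned as stored. RGB/multi-channel files are
#' rejected.
#'
#' @param path path to a single- or multi-page grayscale TIFF.
#' @return a matrix for a single page, or a list of matrices in page
#'   order for a multi-page file; each carries `bits_per_sample` as an
#'   attribute.
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    hilo_abort(sprintf("file not found: %s", path), "io")
  # as.is = TRUE keeps integer samples unscaled but is rejected for
  # float samples, which are already returned as stored
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE),
    error = function(e) {
      if (grepl("as.is", conditionMessage(e), fixed = TRUE))
        tiff::readTIFF(path, all = TRUE, info = TRUE)
      else hilo_abort(sprintf("%s: %s", path, conditionMessage(e)), "io")
    })
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3)
      hilo_abort(sprintf(
        "%s: multi-channel image (samples.per.pixel > 1); grayscale required",
        path), "format")
    m <- matrix(as.numeric(p), nrow(p), ncol(p))
    attr(m, "bits_per_sample") <- attr(p, "bits.per.sample")
    m
  })
  if (length(pages) == 1) pages[[1]] else pages
}

#' Write images as grayscale TIFF
#'
#' The default is uncompressed 32-bit IEEE float samples with no rescaling,
#' so reconstructed values (including negatives) survive a round trip
#' exactly. 8/16-bit integer output is available with optional global
#' min-max normalization.
#'
#' @param image a matrix or a list of matrices (multi-page).
#' @param path output path.
#' @param bits 32 (float, default), 16 or 8 (integer).
#' @param normalize for integer output, scale min-max to the full range;
#'   required when values fall outside the representable range.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, bits = 32, normalize = bits < 32) {
  pages <- if (is.list(image)) image else list(image)
  lapply(pages, check_matrix, name = "image")
  if (bits == 32) {
    write_float_tiff(pages, path)
  } else {
    maxv <- 2^bits - 1
    pages <- lapply(pages, function(p) {
      if (normalize) {
        rg <- range(p)
        if (diff(rg) > 0) p <- (p - rg[1]) / diff(rg) else p <- p * 0
      } else {
        if (min(p) < 0 || max(p) > maxv)
          hilo_abort("values outside integer range; use normalize = TRUE",
                     "data")
        p <- p / maxv
      }
      p
    })
    tiff::writeTIFF(if (length(pages) == 1) pages[[1]] else pages,
                    path, bits.per.sample = bits, compression = "none")
  }
  invisible(path)
}

# Minimal uncompressed little-endian grayscale 32-bit-float TIFF writer
# (single strip per page, chained IFDs). Written by hand because the
# installed TIFF bindings only emit integer samples.
write_float_tiff <- function(pages, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  w4 <- function(x) writeBin(as.integer(x), con, size = 4,
                             endian = "little")
  w2 <- function(x) writeBin(as.integer(x), con, size = 2,
                             endian = "little")
  entry_short <- function(tag, value) { w2(tag); w2(3); w4(1); w2(value); w2(0) }
  entry_long  <- function(tag, value) { w2(tag); w2(4); w4(1); w4(value) }
  writeBin(charToRaw("II"), con); w2(42L)
  n_ifd_bytes <- 2 + 10 * 12 + 4
  # layout: [header 8] then per page: [pixel data][IFD]
  offset <- 8
  data_off <- integer(0); ifd_off <- integer(0)
  for (p in pages) {
    nbytes <- length(p) * 4
    data_off <- c(data_off, offset)
    ifd_off <- c(ifd_off, offset + nbytes)
    offset <- offset + nbytes + n_ifd_bytes
  }
  w4(ifd_off[1])
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    writeBin(as.numeric(t(p)), con, size = 4, endian = "little")
    w2(10L)                               # entry count
    entry_long(256L, ncol(p))             # ImageWidth
    entry_long(257L, nrow(p))             # ImageLength
    entry_short(258L, 32L)                # BitsPerSample
    entry_short(259L, 1L)                 # Compression: none
    entry_short(262L, 1L)                 # Photometric: black is zero
    entry_long(273L, data_off[i])         # StripOffsets
    entry_short(277L, 1L)                 # SamplesPerPixel
    entry_long(278L, nrow(p))             # RowsPerStrip
    entry_long(279L, length(p) * 4)       # StripByteCounts
    entry_short(339L, 3L)                 # SampleFormat: IEEE float
    w4(if (i < length(pages)) ifd_off[i + 1] else 0L)
  }
  invisible(path)
}

#' Pair uniform and speckle z-stacks into a processing manifest
#'
#' Sources may be two directories of single-page TIFFs (matched by sorted
#' filename order) or two multi-page TIFF files (matched by page order).
#' Counts must agree and every pair must share dimensions.
#'
#' @param uniform_source,speckle_source directory or multi-page TIFF path.
#' @param pixel_size_um,sigma optional processing metadata carried along.
#' @return an object of class `stack_manifest`: list with `entries`
#'   (data frame: z, uniform, speckle, page), `n`, `dim`, plus metadata.
#' @export
pair_stacks <- function(uniform_source, speckle_source,
                        pixel_size_um = NULL, sigma = NULL) {
  src <- function(s) {
    if (dir.exists(s)) {
      files <- sort(list.files(s, pattern = "\\.tiff?$", full.names = TRUE,
                               ignore.case = TRUE))
      list(kind = "dir", files = files, n = length(files))
    } else if (file.exists(s)) {
      pages <- read_image(s)
      n <- if (is.list(pages)) length(pages) else 1L
      list(kind = "file", files = s, n = n)
    } else hilo_abort(sprintf("source not found: %s", s), "io")
  }
  u <- src(uniform_source); s <- src(speckle_source)
  if (u$n != s$n)
    hilo_abort(sprintf(
      "pairing error: %d uniform vs %d speckle images", u$n, s$n),
      "pairing")
  if (u$n == 0) hilo_abort("no images found", "pairing")
  entries <- data.frame(
    z = seq_len(u$n),
    uniform = if (u$kind == "dir") u$files else rep(u$files, u$n),
    speckle = if (s$kind == "dir") s$files else rep(s$files, s$n),
    page = seq_len(u$n),
    stringsAsFactors = FALSE)
  # dimension check on first entry of each z
  dims <- NULL
  for (z in seq_len(u$n)) {
    iu <- manifest_slice(entries, z, u$kind, "uniform")
    is <- manifest_slice(entries, z, s$kind, "speckle")
    if (!identical(dim(iu), dim(is)))
      hilo_abort(sprintf("dimension mismatch at z = %d", z), "shape")
    if (is.null(dims)) dims <- dim(iu)
  }
  structure(list(entries = entries, n = u$n, dim = dims,
                 uniform_kind = u$kind, speckle_kind = s$kind,
                 pixel_size_um = pixel_size_um, sigma = sigma),
            class = "stack_manifest")
}

manifest_slice <- function(entries, z, kind, which) {
  path <- entries[[which]][z]
  img <- read_image(path)
  if (is.list(img)) {
    if (kind == "dir") img[[1]] else img[[entries$page[z]]]
  } else img
}

#' Load one z-slice of a manifest as an image pair
#'
#' @param manifest a `stack_manifest`.
#' @param z slice index.
#' @return an [image_pair()].
#' @export
manifest_pair <- function(manifest, z) {
  if (z < 1 || z > manifest$n)
    hilo_abort("z index out of range", "parameter")
  iu <- manifest_slice(manifest$entries, z, manifest$uniform_kind, "uniform")
  is <- manifest_slice(manifest$entries, z, manifest$speckle_kind, "speckle")
  image_pair(iu, is, pixel_size_um = manifest$pixel_size_um)
}

#' @export
print.stack_manifest <- function(x, ...) {
  cat(sprintf("<stack_manifest> %d z-slices, %d x %d px\n",
              x$n, x$dim[1], x$dim[2]))
  invisible(x)
}
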