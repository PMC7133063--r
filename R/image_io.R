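# simulation metadata serialized into image headers (TIFF ImageDescription /
# EDF header keys) so every output file records how to reproduce it
image_metadata <- function(image) {
  g <- image$geometry
  c(detector = g$detector$name,
    wavelength = sprintf("%.12g", g$wavelength),
    distance = sprintf("%.12g", g$distance),
    beam_fast = sprintf("%.12g", g$beam[1]),
    beam_slow = sprintf("%.12g", g$beam[2]),
    exposure = sprintf("%.12g", g$exposure),
    flux = sprintf("%.12g", g$flux),
    concentration = sprintf("%.12g", image$concentration %||% 0),
    seed = sprintf("%s", image$seed %||% NA),
    n_generated = sprintf("%.0f", image$n_generated),
    n_recorded = sprintf("%.0f", image$n_recorded),
    scale = sprintf("%.12g", image$scale %||% NA_real_))
}

metadata_string <- function(image) {
  md <- image_metadata(image)
  paste(sprintf("%s=%s", names(md), md), collapse = "\n")
}

parse_metadata <- function(text) {
  if (is.null(text) || !nzchar(text)) return(list())
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[grepl("=", lines, fixed = TRUE)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  stats::setNames(lapply(kv, function(x) trimws(paste(x[-1], collapse = "="))),
                  trimws(vapply(kv, `[[`, "", 1L)))
}

geometry_from_metadata <- function(md, n_fast, n_slow) {
  det <- tryCatch(detector(md$detector %||% ""), error = function(e) NULL)
  if (is.null(det) || det$n_fast != n_fast || det$n_slow != n_slow)
    det <- detector_model(md$detector %||% "unknown", n_fast, n_slow,
                          as.numeric(md$pixel_size %||% 1e-4))
  saxs_geometry(det,
                distance = as.numeric(md$distance %||% 1),
                wavelength = as.numeric(md$wavelength %||% 1.24e-10),
                beam = c(as.numeric(md$beam_fast %||% ((n_fast - 1) / 2)),
                         as.numeric(md$beam_slow %||% ((n_slow - 1) / 2))),
                exposure = as.numeric(md$exposure %||% 1),
                flux = as.numeric(md$flux %||% 0))
}

#' Write a detector image
#'
#' Lossless export of the integer count grid with the simulation metadata
#' embedded in the header. Two dialects are supported: single-strip
#' uncompressed little-endian 32-bit unsigned TIFF (metadata in the
#' ImageDescription tag) and EDF, the ESRF data format (ASCII key-value
#' header padded to a 512-byte multiple, followed by raw
#' UnsignedInteger/LowByteFirst data).
#'
#' @param image A `detector_image`.
#' @param path Output path.
#' @param format `"tiff"` or `"edf"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, format = NULL) {
  format <- format %||% guess_format(path)
  switch(format,
         tiff = write_tiff_image(image, path),
         edf = write_edf_image(image, path),
         abort(sprintf("Unsupported image format '%s' (use tiff or edf).",
                       format)))
  invisible(path)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) "tiff"
  else if (ext == "edf") "edf"
  else abort(sprintf("Cannot guess image format from '%s'; pass `format`.",
                     path))
}

#' Read a detector image
#'
#' Detects TIFF (via the `tiff` package) or EDF by magic bytes and restores
#' the count grid exactly, along with the geometry recorded in the header.
#'
#' @param path File path.
#' @return A `detector_image`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) abort(sprintf("File '%s' does not exist.", path))
  magic <- readBin(path, "raw", n = 4L)
  if (length(magic) >= 4L && rawToChar(magic[1:2]) %in% c("II", "MM"))
    read_tiff_image(path)
  else if (length(magic) >= 1L && rawToChar(magic[1]) == "{")
    read_edf_image(path)
  else abort(sprintf("'%s' is neither a TIFF nor an EDF image.", path))
}

# --- TIFF ------------------------------------------------------------------
# Minimal baseline writer: II byte order, one uncompressed strip of uint32
# samples, ImageDescription carrying the metadata. Images written here are
# read back through tiff::readTIFF, which therefore cross-checks the writer
# in every round trip.

tiff_entry <- function(tag, type, count, value_raw) {
  c(writeBin(as.integer(tag), raw(), size = 2L, endian = "little"),
    writeBin(as.integer(type), raw(), size = 2L, endian = "little"),
    writeBin(as.integer(count), raw(), size = 4L, endian = "little"),
    value_raw)
}

le4 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")
le2pad <- function(x) c(writeBin(as.integer(x), raw(), size = 2L,
                                 endian = "little"), as.raw(c(0, 0)))

write_tiff_image <- function(image, path) {
  counts <- image$counts
  if (any(counts < 0) || any(counts >= 2^31))
    abort("counts must fit an unsigned 32-bit integer.")
  w <- nrow(counts)   # fast axis = image width
  h <- ncol(counts)
  desc_raw <- c(charToRaw(metadata_string(image)), as.raw(0))  # NUL-terminated
  data_off <- 8L
  data_len <- 4L * w * h
  desc_off <- data_off + data_len
  ifd_off <- desc_off + length(desc_raw)
  if (ifd_off %% 2L == 1L) { desc_raw <- c(desc_raw, as.raw(0)); ifd_off <- ifd_off + 1L }
  entries <- list(
    tiff_entry(256L, 4L, 1L, le4(w)),               # ImageWidth
    tiff_entry(257L, 4L, 1L, le4(h)),               # ImageLength
    tiff_entry(258L, 3L, 1L, le2pad(32L)),          # BitsPerSample
    tiff_entry(259L, 3L, 1L, le2pad(1L)),           # Compression: none
    tiff_entry(262L, 3L, 1L, le2pad(1L)),           # Photometric: BlackIsZero
    tiff_entry(270L, 2L, length(desc_raw), le4(desc_off)),  # ImageDescription
    tiff_entry(273L, 4L, 1L, le4(data_off)),        # StripOffsets
    tiff_entry(277L, 3L, 1L, le2pad(1L)),           # SamplesPerPixel
    tiff_entry(278L, 4L, 1L, le4(h)),               # RowsPerStrip
    tiff_entry(279L, 4L, 1L, le4(data_len)),        # StripByteCounts
    tiff_entry(339L, 3L, 1L, le2pad(1L)))           # SampleFormat: unsigned
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), writeBin(42L, raw(), size = 2L, endian = "little"),
             le4(ifd_off)), con)
  # pixel rows follow the slow axis; column-major counts already serialize
  # fast-axis-first
  writeBin(as.integer(counts), con, size = 4L, endian = "little")
  writeBin(desc_raw, con)
  writeBin(writeBin(length(entries), raw(), size = 2L, endian = "little"), con)
  for (e in entries) writeBin(e, con)
  writeBin(le4(0L), con)                            # no next IFD
  invisible(path)
}

read_tiff_image <- function(path) {
  # R character vectors cannot hold the tag's terminating NUL, so the tiff
  # package warns while stripping it; the value itself is intact
  img <- withCallingHandlers(
    tryCatch(tiff::readTIFF(path, as.is = TRUE, info = TRUE),
             error = function(e)
               abort(sprintf("'%s': malformed TIFF (%s).", path,
                             conditionMessage(e)))),
    warning = function(w) {
      if (grepl("ImageDescription", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  m <- t(round(unclass(img)))        # readTIFF returns height x width
  counts <- matrix(as.integer(m), nrow(m), ncol(m))
  md <- parse_metadata(attr(img, "description"))
  g <- geometry_from_metadata(md, nrow(counts), ncol(counts))
  num <- function(x, default) {
    v <- suppressWarnings(as.numeric(x %||% default))
    if (is.na(v)) default else v
  }
  new_detector_image(counts, g,
                     n_generated = num(md$n_generated, sum(counts)),
                     n_recorded = num(md$n_recorded, sum(counts)),
                     concentration = num(md$concentration, 0),
                     seed = md$seed %||% NA,
                     scale = suppressWarnings(as.numeric(md$scale %||% NA)))
}

# --- EDF -------------------------------------------------------------------

write_edf_image <- function(image, path) {
  counts <- image$counts
  if (any(counts < 0) || any(counts >= 2^31))
    abort("counts must fit an unsigned 32-bit integer.")
  w <- nrow(counts); h <- ncol(counts)
  md <- image_metadata(image)
  keys <- c(
    "HeaderID = EH:000001:000000:000000",
    "Image = 1",
    "ByteOrder = LowByteFirst",
    "DataType = UnsignedInteger",
    sprintf("Dim_1 = %d", w),
    sprintf("Dim_2 = %d", h),
    sprintf("Size = %d", 4L * w * h),
    sprintf("PixelSize = %.12g", image$geometry$detector$pixel_size),
    sprintf("%s = %s", names(md), md))
  body <- paste0("{\n", paste0(keys, " ;\n", collapse = ""))
  pad <- 512L - ((nchar(body) + 2L) %% 512L)
  if (pad == 512L) pad <- 0L
  header <- paste0(body, strrep(" ", pad), "}\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(as.integer(counts), con, size = 4L, endian = "little")
  invisible(path)
}

read_edf_image <- function(path) {
  raw_all <- readBin(path, "raw", n = file.size(path))
  close_idx <- which(raw_all == charToRaw("}"))[1]
  if (is.na(close_idx)) abort(sprintf("'%s': malformed EDF (no header end).", path))
  header <- rawToChar(raw_all[seq_len(close_idx)])
  lines <- strsplit(header, "\n", fixed = TRUE)[[1]]
  lines <- sub("\\s*;\\s*$", "", lines)
  md <- parse_metadata(paste(lines, collapse = "\n"))
  w <- as.integer(md$Dim_1); h <- as.integer(md$Dim_2)
  if (is.na(w) || is.na(h)) abort(sprintf("'%s': malformed EDF (no dimensions).", path))
  data_start <- close_idx + 1L
  if (data_start <= length(raw_all) && raw_all[data_start] == charToRaw("\n"))
    data_start <- data_start + 1L
  need <- 4L * w * h
  if (length(raw_all) - data_start + 1L < need)
    abort(sprintf("'%s': truncated EDF payload.", path))
  vals <- readBin(raw_all[seq.int(data_start, data_start + need - 1L)],
                  "integer", n = w * h, size = 4L, endian = "little")
  counts <- matrix(vals, w, h)
  md$pixel_size <- md$pixel_size %||% md$PixelSize
  g <- geometry_from_metadata(md, w, h)
  num <- function(x, default) {
    v <- suppressWarnings(as.numeric(x %||% default))
    if (is.na(v)) default else v
  }
  new_detector_image(counts, g,
                     n_generated = num(md$n_generated, sum(counts)),
                     n_recorded = num(md$n_recorded, sum(counts)),
                     concentration = num(md$concentration, 0),
                     seed = md$seed %||% NA,
                     scale = suppressWarnings(as.numeric(md$scale %||% NA)))
}
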