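new_mask_image <- function(excluded, detector) {
  stopifnot(is.matrix(excluded), is.logical(excluded))
  structure(list(excluded = excluded, detector = detector),
            class = "mask_image")
}

#' @export
print.mask_image <- function(x, ...) {
  cat(sprintf("<mask_image> %d x %d px, %s excluded\n",
              nrow(x$excluded), ncol(x$excluded),
              format(sum(x$excluded), big.mark = ",")))
  invisible(x)
}

#' Build a beamstop + module-gap mask
#'
#' Excludes every pixel whose centre lies within the beamstop disc (radius
#' `beamstop_diameter / 2` around `beam + offset`) and every pixel inside an
#' insensitive module gap. The gap pattern is fixed by the detector layout;
#' the beamstop disc translates rigidly with the offset.
#'
#' @param detector A `saxs_detector` or catalogue name.
#' @param beam Beam centre in continuous pixel coordinates `(fast, slow)`.
#' @param beamstop_diameter Beamstop diameter in metres (default 3 mm).
#' @param offset Length-2 pixel offset added to the beam position, to shift
#'   the mask for a different beam location on the image.
#' @return A `mask_image` whose `excluded` grid is `TRUE` where pixels are
#'   dropped from averaging.
#' @examples
#' m <- build_mask(detector_model("toy", 32, 32, 172e-6), beam = c(15.5, 15.5),
#'                 beamstop_diameter = 1e-3)
#' sum(m$excluded)
#' @export
build_mask <- function(detector, beam, beamstop_diameter = 3e-3,
                       offset = c(0, 0)) {
  if (is.character(detector)) detector <- detector(detector)
  if (beamstop_diameter < 0) abort("`beamstop_diameter` must be >= 0.")
  excluded <- gap_matrix(detector)
  r_px <- (beamstop_diameter / 2) / detector$pixel_size
  if (r_px > 0) {
    cx <- beam[1] + offset[1]
    cy <- beam[2] + offset[2]
    d2 <- outer((0:(detector$n_fast - 1L) - cx)^2,
                (0:(detector$n_slow - 1L) - cy)^2, "+")
    excluded <- excluded | (d2 <= r_px^2)
  }
  new_mask_image(excluded, detector)
}

#' Radial bins blinded by the beamstop or the mask
#'
#' A radial bin `i` (the annulus `[i - 0.5, i + 0.5)` in pixel-radius units)
#' is excluded when the annulus intersects the beamstop disc -- even the bin
#' whose outer part peeks beyond the disc edge, since its average would be
#' biased by the shadowed inner pixels -- and additionally when no live pixel
#' at all falls in it.
#'
#' @param mask A `mask_image` (or `NULL` for no pixel mask).
#' @param beam Beam centre in pixel coordinates.
#' @param beamstop_diameter Metres.
#' @param n_bins Number of radial bins considered (bins `0 ... n_bins - 1`).
#' @return Sorted integer vector of excluded bin indices.
#' @export
excluded_bins <- function(mask, beam, beamstop_diameter = 0,
                          n_bins = NULL) {
  det <- mask$detector
  n_bins <- n_bins %||% {
    g <- list(detector = det, beam = beam)
    cx <- c(0, det$n_fast - 1); cy <- c(0, det$n_slow - 1)
    as.integer(floor(max(sqrt(outer((cx - beam[1])^2, (cy - beam[2])^2, "+"))) + 0.5)) + 1L
  }
  r_px <- (beamstop_diameter / 2) / det$pixel_size
  disc <- if (r_px > 0) 0:min(n_bins - 1L, floor(r_px + 0.5)) else integer()
  acc <- cpp_radial_accumulate(matrix(0L, det$n_fast, det$n_slow),
                               mask$excluded, TRUE, beam[1], beam[2], n_bins)
  empty <- which(acc$npix == 0L) - 1L
  sort(unique(c(disc, empty)))
}

msk_row_bytes <- function(n_fast) 4L * ((n_fast + 31L) %/% 32L)

#' Write / read a FIT2D binary mask
#'
#' The de-facto .MSK layout: a 1024-byte header starting with the ASCII
#' signature `MASK` and the image dimensions as little-endian 32-bit
#' integers at byte offsets 16 and 20 (reserved bytes written as zeros),
#' followed by one bit per pixel, least-significant bit first, each row
#' padded to a 32-bit boundary.
#'
#' @param mask A `mask_image`.
#' @param path File path.
#' @param detector Detector to attach on reading (defaults to a gapless
#'   model of the stored dimensions).
#' @return `write_msk` returns `path` invisibly; `read_msk` a `mask_image`.
#' @export
write_msk <- function(mask, path) {
  nf <- nrow(mask$excluded); ns <- ncol(mask$excluded)
  header <- raw(1024L)
  header[1:4] <- charToRaw("MASK")
  header[17:24] <- writeBin(c(nf, ns), raw(), size = 4L, endian = "little")
  row_bits <- 8L * msk_row_bytes(nf)
  bits <- matrix(FALSE, row_bits, ns)
  bits[seq_len(nf), ] <- mask$excluded
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(header, con)
  writeBin(packBits(as.vector(bits), type = "raw"), con)
  invisible(path)
}

#' @rdname write_msk
#' @export
read_msk <- function(path, detector = NULL) {
  raw_all <- readBin(path, "raw", n = file.size(path))
  if (length(raw_all) < 1024L || !identical(raw_all[1:4], charToRaw("MASK")))
    abort(sprintf("'%s' is not a FIT2D .MSK file (bad signature).", path))
  dims <- readBin(raw_all[17:24], "integer", n = 2L, size = 4L,
                  endian = "little")
  nf <- dims[1]; ns <- dims[2]
  if (nf < 1L || ns < 1L) abort(sprintf("'%s': invalid mask dimensions.", path))
  need <- msk_row_bytes(nf) * ns
  payload <- raw_all[-seq_len(1024L)]
  if (length(payload) < need)
    abort(sprintf("'%s': truncated payload (%d of %d bytes).",
                  path, length(payload), need))
  bits <- as.logical(rawToBits(payload[seq_len(need)]))
  excluded <- matrix(bits, nrow = 8L * msk_row_bytes(nf))[seq_len(nf), ,
                                                          drop = FALSE]
  dim(excluded) <- c(nf, ns)
  detector <- detector %||% detector_model("unknown", nf, ns, 1e-4)
  new_mask_image(excluded, detector)
}

#' Export a mask as a 0/1 TIFF image
#'
#' @param mask A `mask_image`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(mask, path) {
  img <- new_detector_image(
    matrix(as.integer(mask$excluded), nrow(mask$excluded)),
    saxs_geometry(mask$detector, distance = 1,
                  beam = c(0, 0), exposure = 0, flux = 0),
    n_generated = 0, n_recorded = 0)
  write_image(img, path, format = "tiff")
}
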