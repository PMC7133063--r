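#' Radially average a detector image
#'
#' Collapses the isotropic 2D pattern into a 1D curve: each live (unmasked)
#' pixel is assigned to the radial bin given by its nearest-integer pixel
#' distance to the beam. For bin `i` with live-pixel counts `c_k`,
#' `I_i = sum(c_k) / (npix_i * T)` and, by Poisson propagation of the summed
#' counts, `sigma_i = sqrt(sum(c_k)) / (npix_i * T)` where `T` is the
#' exposure. Empty sums use an error floor of `sqrt(1)` -- standard
#' counting-statistics practice that keeps zero-count bins usable in
#' chi-squared comparisons. Rates (per second) rather than raw counts are
#' stored so frames of different exposure subtract correctly.
#'
#' Bins whose annulus intersects the beamstop disc, and bins without live
#' pixels, are dropped (see [excluded_bins()]).
#'
#' @param image A `detector_image`.
#' @param mask Optional `mask_image` (beamstop + gaps). When omitted, every
#'   pixel is live.
#' @param beamstop_diameter Metres; used for the annulus-overlap bin rule
#'   (default 0: no bins blinded).
#' @return A `reduced_curve` tibble with columns `bin`, `s` (nm^-1), `I`
#'   (counts / pixel / s), `sigma`, `npix`, and attributes `exposure` and
#'   `scale` (the absolute-intensity-to-rate factor of the simulation, if
#'   known).
#' @export
radial_average <- function(image, mask = NULL, beamstop_diameter = 0) {
  g <- image$geometry
  det <- g$detector
  if (!is.null(mask) &&
      !all(dim(mask$excluded) == dim(image$counts)))
    abort("mask and image dimensions differ.")
  t_exp <- g$exposure
  if (t_exp <= 0) abort("image exposure must be > 0 to form rates.")
  n_bins <- max_bin_index(g) + 1L
  acc <- cpp_radial_accumulate(image$counts,
                               if (is.null(mask)) matrix(FALSE, 1, 1)
                               else mask$excluded,
                               !is.null(mask), g$beam[1], g$beam[2], n_bins)
  bin <- seq_len(n_bins) - 1L
  keep <- acc$npix >= 1L
  r_px <- (beamstop_diameter / 2) / det$pixel_size
  if (r_px > 0) keep <- keep & (bin - 0.5 > r_px)
  if (!any(keep)) abort("no live pixels: the reduced curve is empty.")
  bin <- bin[keep]
  csum <- acc$sum[keep]
  npix <- acc$npix[keep]
  out <- tibble(bin = as.integer(bin),
                s = s_of_radius(bin * det$pixel_size, g),
                I = csum / (npix * t_exp),
                sigma = sqrt(pmax(csum, 1)) / (npix * t_exp),
                npix = as.integer(npix))
  new_reduced_curve(out, exposure = t_exp, scale = image$scale %||% NA_real_)
}

new_reduced_curve <- function(df, exposure, scale = NA_real_,
                              concentration = NA_real_) {
  class(df) <- unique(c("reduced_curve", class(df)))
  attr(df, "exposure") <- exposure
  attr(df, "scale") <- scale
  attr(df, "concentration") <- concentration
  df
}

#' Subtract background and scale by concentration
#'
#' `I_sub = (I_sample - I_background) / c` per bin, with
#' `sigma_sub = sqrt(sigma_s^2 + sigma_b^2) / c`. Both curves must be on the
#' identical bin/s grid; exposures may differ since reduced curves store
#' rates.
#'
#' @param sample,background `reduced_curve`s on a common grid.
#' @param concentration mg/ml, > 0.
#' @return A `reduced_curve` on the sample's grid; its `scale` attribute is
#'   inherited from the sample frame, so the result is directly comparable
#'   to the absolute-scale input curve times `scale`.
#' @export
subtract_and_scale <- function(sample, background, concentration) {
  if (concentration <= 0) abort("`concentration` must be > 0.")
  if (nrow(sample) != nrow(background) ||
      any(sample$bin != background$bin) ||
      any(abs(sample$s - background$s) > 1e-9 * pmax(sample$s, 1e-12)))
    abort("sample and background are not on the same bin grid.")
  out <- tibble(bin = sample$bin, s = sample$s,
                I = (sample$I - background$I) / concentration,
                sigma = sqrt(sample$sigma^2 + background$sigma^2) / concentration,
                npix = sample$npix)
  new_reduced_curve(out, exposure = attr(sample, "exposure"),
                    scale = attr(sample, "scale"),
                    concentration = concentration)
}

#' Write / read a reduced curve (.dat)
#'
#' Three-column ASCII `s I sigma` with `#` header lines -- the de-facto SAXS
#' exchange format. Values are preserved to 12 significant digits across a
#' round trip.
#'
#' @param curve A `reduced_curve` (any tibble with `s`, `I`, `sigma`).
#' @param path File path.
#' @param header Optional extra header lines.
#' @return `write_dat` returns `path` invisibly; `read_dat` a
#'   `reduced_curve` tibble (without `bin`/`npix`, which are not part of the
#'   exchange format).
#' @export
write_dat <- function(curve, path, header = NULL) {
  hdr <- c("# saxsim reduced curve: s (nm^-1), I (counts/pixel/s), sigma",
           "# sigma floor: empty bins carry sqrt(1) summed-count error",
           sprintf("# exposure = %.12g", attr(curve, "exposure") %||% NA_real_),
           sprintf("# scale = %.12g", attr(curve, "scale") %||% NA_real_),
           if (!is.null(header)) paste0("# ", header))
  writeLines(c(hdr, sprintf("%.12e %.12e %.12e", curve$s, curve$I,
                            curve$sigma)), path)
  invisible(path)
}

#' @rdname write_dat
#' @export
read_dat <- function(path) {
  rows <- read_numeric_rows(path, min_cols = 3L, max_cols = 3L)
  if (nrow(rows) < 1L) abort(sprintf("'%s': no data rows.", path))
  hdr <- grep("^#", readLines(path, warn = FALSE), value = TRUE)
  grab <- function(key) {
    m <- grep(sprintf("^#\\s*%s\\s*=", key), hdr, value = TRUE)
    if (length(m)) suppressWarnings(as.numeric(sub(".*=\\s*", "", m[1])))
    else NA_real_
  }
  out <- tibble(s = rows[, 1], I = rows[, 2], sigma = rows[, 3])
  new_reduced_curve(out, exposure = grab("exposure"), scale = grab("scale"))
}
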