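#' Detector catalogue
#'
#' Named photon-counting detector geometries (Pilatus and Eiger families)
#' bundled with the package as a plain CSV, so that new detectors can be added
#' without a code change. Dimensions follow the vendors' published module
#' layouts: a detector is a rectangular tiling of sensitive modules separated
#' by insensitive gap strips.
#'
#' @return A tibble with one row per detector: `name`, pixel counts `n_fast`,
#'   `n_slow`, `pixel_size` (m), module sizes `module_fast`, `module_slow`
#'   (pixels) and gap widths `gap_fast`, `gap_slow` (pixels).
#' @examples
#' detector_catalogue()
#' @export
detector_catalogue <- function() {
  if (is.null(the$catalogue)) {
    path <- system.file("extdata", "detectors.csv", package = "saxsim",
                        mustWork = TRUE)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    the$catalogue <- as_tibble(df)
  }
  the$catalogue
}

#' Define a detector model
#'
#' Constructs a detector description from explicit dimensions. The pixel grid
#' must be an exact tiling of `k` modules and `k - 1` gaps along each axis.
#' Use [detector()] to look up a named catalogue entry.
#'
#' @param name Identifier string.
#' @param n_fast,n_slow Pixel counts along the fast and slow axis.
#' @param pixel_size Pixel edge length in metres.
#' @param module_fast,module_slow Module size in pixels along each axis.
#'   Defaults to the full detector (a monolithic, gapless detector).
#' @param gap_fast,gap_slow Gap width in pixels between adjacent modules.
#' @return A `saxs_detector` object.
#' @examples
#' detector_model("toy", 64, 64, 100e-6)
#' @export
detector_model <- function(name, n_fast, n_slow, pixel_size,
                           module_fast = n_fast, module_slow = n_slow,
                           gap_fast = 0L, gap_slow = 0L) {
  n_fast <- as.integer(n_fast); n_slow <- as.integer(n_slow)
  module_fast <- as.integer(module_fast); module_slow <- as.integer(module_slow)
  gap_fast <- as.integer(gap_fast); gap_slow <- as.integer(gap_slow)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    abort("`pixel_size` must be a single positive length in metres.")
  check_tiling(n_fast, module_fast, gap_fast, "fast")
  check_tiling(n_slow, module_slow, gap_slow, "slow")
  structure(
    list(name = as.character(name), n_fast = n_fast, n_slow = n_slow,
         pixel_size = pixel_size,
         module_fast = module_fast, module_slow = module_slow,
         gap_fast = gap_fast, gap_slow = gap_slow),
    class = "saxs_detector")
}

check_tiling <- function(n, module, gap, axis) {
  # n = k*module + (k-1)*gap must hold for an integer k >= 1
  k <- (n + gap) / (module + gap)
  if (module < 1L || gap < 0L || k < 1 || k != round(k))
    abort(sprintf(
      "%d pixels (%s axis) is not a tiling of %d-pixel modules with %d-pixel gaps.",
      n, axis, module, gap))
  invisible(as.integer(k))
}

#' Look up a detector by name
#'
#' @param name Catalogue name, e.g. `"pilatus6m"` (see [detector_catalogue()]).
#' @return A `saxs_detector` object.
#' @examples
#' detector("pilatus6m")
#' @export
detector <- function(name) {
  cat <- detector_catalogue()
  hit <- cat[cat$name == tolower(name), ]
  if (nrow(hit) != 1L)
    abort(sprintf("Unknown detector '%s'. Available: %s.",
                  name, paste(cat$name, collapse = ", ")))
  detector_model(hit$name, hit$n_fast, hit$n_slow, hit$pixel_size,
                 hit$module_fast, hit$module_slow, hit$gap_fast, hit$gap_slow)
}

#' @export
print.saxs_detector <- function(x, ...) {
  cat(sprintf("<saxs_detector> %s: %d x %d px of %g um, modules %d x %d, gaps %d/%d px\n",
              x$name, x$n_fast, x$n_slow, x$pixel_size * 1e6,
              x$module_fast, x$module_slow, x$gap_fast, x$gap_slow))
  invisible(x)
}

# TRUE for 0-based pixel indices lying inside an insensitive gap strip
in_gap <- function(idx, module, gap) {
  if (gap == 0L) return(rep(FALSE, length(idx)))
  (idx %% (module + gap)) >= module
}

# logical n_fast x n_slow matrix of gap pixels
gap_matrix <- function(detector) {
  gf <- in_gap(0:(detector$n_fast - 1L), detector$module_fast, detector$gap_fast)
  gs <- in_gap(0:(detector$n_slow - 1L), detector$module_slow, detector$gap_slow)
  outer(gf, gs, "|")
}

#' Experiment geometry
#'
#' Bundles a detector with the virtual beamline setup: sample-to-detector
#' distance, X-ray wavelength, continuous beam position on the detector
#' plane, exposure time and flux. Units follow beamline convention: metres,
#' seconds and events per second. The beam position is given in continuous
#' pixel coordinates -- pixel `(i, j)` has its centre at `(i, j)` and covers
#' `[i - 0.5, i + 0.5) x [j - 0.5, j + 0.5)`, 0-based -- and may lie off the
#' pixel grid.
#'
#' @param detector A `saxs_detector`, or a catalogue name passed to
#'   [detector()].
#' @param distance Sample-to-detector distance in metres.
#' @param wavelength X-ray wavelength in metres. The default 1.24e-10 m
#'   (0.124 nm, 10 keV) is the package's reference wavelength.
#' @param beam Numeric length-2, beam centre in pixel coordinates
#'   `(fast, slow)`. Default: fast axis centred and 173 pixels from the slow
#'   edge for the Pilatus 6M (the configuration under which the package's
#'   reference angular ranges are computed), otherwise the detector centre.
#' @param exposure Exposure time in seconds.
#' @param flux Expected event rate of the pure background in events/s.
#' @return A `saxs_geometry` object.
#' @examples
#' saxs_geometry("pilatus6m", distance = 6.0)
#' @export
saxs_geometry <- function(detector, distance, wavelength = 1.24e-10,
                          beam = NULL, exposure = 1, flux = 1e7) {
  if (is.character(detector)) detector <- detector(detector)
  stopifnot(inherits(detector, "saxs_detector"))
  if (!is.numeric(distance) || distance <= 0) abort("`distance` must be > 0 m.")
  if (!is.numeric(wavelength) || wavelength <= 0) abort("`wavelength` must be > 0 m.")
  if (exposure < 0) abort("`exposure` must be >= 0 s.")
  if (flux < 0) abort("`flux` must be >= 0 events/s.")
  if (is.null(beam)) {
    beam <- if (identical(detector$name, "pilatus6m"))
      c((detector$n_fast - 1) / 2, 173)
    else
      c((detector$n_fast - 1) / 2, (detector$n_slow - 1) / 2)
  }
  if (length(beam) != 2L || !is.numeric(beam))
    abort("`beam` must be numeric (fast, slow) pixel coordinates.")
  structure(
    list(detector = detector, distance = distance, wavelength = wavelength,
         beam = as.numeric(beam), exposure = exposure, flux = flux),
    class = "saxs_geometry")
}

#' @export
print.saxs_geometry <- function(x, ...) {
  cat(sprintf(
    "<saxs_geometry> %s at D = %g m, lambda = %g nm, beam (%g, %g) px, %g s, %g ev/s\n",
    x$detector$name, x$distance, x$wavelength * 1e9,
    x$beam[1], x$beam[2], x$exposure, x$flux))
  invisible(x)
}
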