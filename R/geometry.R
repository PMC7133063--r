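#' Momentum transfer at a detector radius
#'
#' For elastic scattering onto a flat detector normal to the beam, a point at
#' distance `r` from the beam centre is hit at scattering angle
#' `2*theta = atan(r / D)`, so the momentum transfer is
#' `s = (4*pi / lambda) * sin(atan(r / D) / 2)`. Wavelength and distance come
#' from `geometry`; the result is returned in inverse nanometres.
#'
#' @param r Radius on the detector plane in metres (vectorized).
#' @param geometry A [saxs_geometry()].
#' @return Momentum transfer in nm^-1, strictly increasing in `r`.
#' @examples
#' g <- saxs_geometry("pilatus6m", distance = 6.0)
#' s_of_radius(10 * 172e-6, g)  # radial bin 10
#' @export
s_of_radius <- function(r, geometry) {
  if (any(r < 0)) abort("`r` must be >= 0.")
  lambda_nm <- geometry$wavelength * 1e9
  (4 * pi / lambda_nm) * sin(atan(r / geometry$distance) / 2)
}

#' Detector radius at a momentum transfer
#'
#' Exact inverse of [s_of_radius()]: `theta = asin(s * lambda / (4*pi))`,
#' `r = D * tan(2 * theta)`. Only momentum transfers that scatter onto the
#' (forward, finite) detector plane have a radius, i.e. `2*theta < pi/2`.
#'
#' @param s Momentum transfer in nm^-1 (vectorized).
#' @param geometry A [saxs_geometry()].
#' @return Radius in metres.
#' @export
radius_of_s <- function(s, geometry) {
  lambda_nm <- geometry$wavelength * 1e9
  s_max <- 4 * pi / lambda_nm
  if (any(s < 0) || any(s >= s_max))
    abort(sprintf("`s` must lie in [0, 4*pi/lambda) = [0, %g) nm^-1.", s_max))
  theta <- asin(s * lambda_nm / (4 * pi))
  if (any(2 * theta >= pi / 2))
    abort("`s` scatters beyond the detector plane (2*theta >= 90 deg).")
  geometry$distance * tan(2 * theta)
}

#' Maximum radial bin index
#'
#' Pixels are assigned to radial bins by their centre distance to the beam in
#' pixel units, rounded to the nearest integer; bin `i` is the annulus
#' `[i - 0.5, i + 0.5)`. The largest centre distance is attained at one of the
#' four corner pixels of the grid.
#'
#' @param geometry A [saxs_geometry()].
#' @return Integer index of the outermost radial bin.
#' @export
max_bin_index <- function(geometry) {
  det <- geometry$detector
  cx <- c(0, det$n_fast - 1)
  cy <- c(0, det$n_slow - 1)
  d <- sqrt(outer((cx - geometry$beam[1])^2, (cy - geometry$beam[2])^2, "+"))
  as.integer(floor(max(d) + 0.5))
}

# radius (m) of the farthest pixel *corner*: support of the on-detector events
max_corner_radius <- function(geometry) {
  det <- geometry$detector
  cx <- c(-0.5, det$n_fast - 0.5)
  cy <- c(-0.5, det$n_slow - 0.5)
  d <- sqrt(outer((cx - geometry$beam[1])^2, (cy - geometry$beam[2])^2, "+"))
  max(d) * det$pixel_size
}

#' Angular axis of the radial bins
#'
#' One row per radial bin `i`, carrying the momentum transfer assigned to the
#' bin, `s_i = s_of_radius(i * pixel_size)`. This is the axis against which
#' radially averaged curves are reported.
#'
#' @param geometry A [saxs_geometry()].
#' @param first_bin,last_bin Inclusive bin range; defaults to the whole
#'   detector, bin 0 through [max_bin_index()].
#' @return A tibble with columns `bin` and `s` (nm^-1), strictly increasing.
#' @examples
#' g <- saxs_geometry("pilatus6m", distance = 6.0)
#' build_axis(g, 10, 12)
#' @export
build_axis <- function(geometry, first_bin = 0L,
                       last_bin = max_bin_index(geometry)) {
  if (first_bin < 0 || last_bin < first_bin)
    abort("need 0 <= first_bin <= last_bin.")
  bin <- seq.int(first_bin, last_bin)
  tibble(bin = as.integer(bin),
         s = s_of_radius(bin * geometry$detector$pixel_size, geometry))
}

#' Write / read an axis file
#'
#' Two-column ASCII (bin index, s in nm^-1) with `#` header lines recording
#' wavelength, distance and detector name.
#'
#' @param axis Tibble from [build_axis()].
#' @param path File path.
#' @param geometry Optional [saxs_geometry()] whose parameters are recorded in
#'   the header.
#' @return `write_axis` returns `path` invisibly; `read_axis` returns the
#'   axis tibble.
#' @export
write_axis <- function(axis, path, geometry = NULL) {
  hdr <- "# saxsim axis file: bin index, momentum transfer s (nm^-1)"
  if (!is.null(geometry)) {
    hdr <- c(hdr, sprintf("# detector = %s", geometry$detector$name),
             sprintf("# wavelength = %.12g", geometry$wavelength),
             sprintf("# distance = %.12g", geometry$distance))
  }
  writeLines(c(hdr, sprintf("%d %.12e", axis$bin, axis$s)), path)
  invisible(path)
}

#' @rdname write_axis
#' @export
read_axis <- function(path) {
  rows <- read_numeric_rows(path, min_cols = 2L)
  if (nrow(rows) < 1L) abort(sprintf("No axis rows found in '%s'.", path))
  tibble(bin = as.integer(rows[, 1]), s = rows[, 2])
}

# shared whitespace-separated numeric table reader: skips '#' comments and any
# row whose first `min_cols` fields are not numeric (e.g. CRYSOL headers)
read_numeric_rows <- function(path, min_cols = 2L, max_cols = 3L) {
  if (!file.exists(path)) abort(sprintf("File '%s' does not exist.", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  toks <- strsplit(trimws(lines), "\\s+")
  out <- matrix(NA_real_, length(toks), max_cols)
  keep <- logical(length(toks))
  for (k in seq_along(toks)) {
    v <- suppressWarnings(as.numeric(toks[[k]]))
    if (length(v) >= min_cols && !anyNA(v[seq_len(min_cols)])) {
      keep[k] <- TRUE
      n <- min(length(v), max_cols)
      out[k, seq_len(n)] <- v[seq_len(n)]
    }
  }
  out[keep, , drop = FALSE]
}
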