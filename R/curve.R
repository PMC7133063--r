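#' Scattering curve
#'
#' A 1D scattering curve `I(s)` on absolute scale (per unit concentration for
#' sample curves), stored as a tibble with momentum transfer `s` in nm^-1.
#' An optional `sigma` column is carried through but ignored by the
#' simulator -- simulated noise is purely Poisson counting noise.
#'
#' @param s Strictly increasing momentum-transfer grid, nm^-1, `s[1] >= 0`.
#' @param I Nonnegative intensities, same length as `s` (at least 2 points).
#' @param sigma Optional uncertainties.
#' @return A `saxs_curve` tibble.
#' @export
saxs_curve <- function(s, I, sigma = NULL) {
  if (length(s) != length(I) || length(s) < 2L)
    abort("`s` and `I` must have equal length >= 2.")
  if (s[1] < 0 || any(diff(s) <= 0))
    abort("`s` must be strictly increasing with s[1] >= 0.")
  if (any(!is.finite(I)) || any(I < 0))
    abort("`I` must be finite and >= 0 (intensities are probability weights).")
  out <- if (is.null(sigma)) tibble(s = as.numeric(s), I = as.numeric(I))
         else tibble(s = as.numeric(s), I = as.numeric(I),
                     sigma = as.numeric(sigma))
  class(out) <- c("saxs_curve", class(out))
  out
}

#' Read a calculated scattering curve
#'
#' Reads a whitespace-separated two- or three-column file (momentum transfer,
#' intensity on absolute scale, optional uncertainty). Header or footer lines
#' whose first two fields are not numeric -- such as CRYSOL banners -- and
#' `#` comments are skipped. By default the momentum-transfer column is
#' interpreted in inverse angstroms, the convention of calculated-curve
#' files, and converted to the package-internal nm^-1 (factor 10).
#'
#' @param path File path.
#' @param unit `"angstrom"` (default) or `"nm"`: unit of the s column in the
#'   file.
#' @return A [saxs_curve()].
#' @export
read_curve <- function(path, unit = c("angstrom", "nm")) {
  unit <- match.arg(unit)
  rows <- read_numeric_rows(path, min_cols = 2L, max_cols = 3L)
  if (nrow(rows) < 2L)
    abort(sprintf("'%s': need at least 2 parseable data rows.", path))
  s <- rows[, 1] * if (unit == "angstrom") 10 else 1
  if (any(diff(s) <= 0))
    abort(sprintf("'%s': momentum-transfer column must be strictly increasing.", path))
  sigma <- rows[, 3]
  if (anyNA(sigma)) sigma <- NULL
  saxs_curve(s, rows[, 2], sigma = sigma)
}

#' Write a scattering curve
#'
#' @param curve A [saxs_curve()].
#' @param path File path.
#' @param unit Unit for the s column on disk (default inverse angstroms).
#' @param header Optional character vector of extra `#` header lines.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path, unit = c("angstrom", "nm"), header = NULL) {
  unit <- match.arg(unit)
  s <- curve$s / if (unit == "angstrom") 10 else 1
  hdr <- c(sprintf("# saxsim scattering curve; s in %s^-1, I absolute scale",
                   if (unit == "angstrom") "A" else "nm"),
           if (!is.null(header)) paste0("# ", header))
  body <- if (!is.null(curve[["sigma"]]))
    sprintf("%.12e %.12e %.12e", s, curve$I, curve[["sigma"]])
  else sprintf("%.12e %.12e", s, curve$I)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Double-exponential background model
#'
#' The default "flat" instrumental background,
#' `I_bg(s) = a1 * exp(-b1 * s) + a2 * exp(-b2 * s)`: nearly flat across the
#' detector with a mild low-angle rise. The default coefficients are package
#' choices, always overridable and recorded in output headers.
#'
#' @param a1,a2 Amplitudes (absolute intensity units), >= 0, `a1 + a2 > 0`.
#' @param b1,b2 Decay constants in nm (multiplying s in nm^-1), >= 0.
#' @return A `saxs_background` object.
#' @examples
#' bg <- background_model()
#' eval_background(bg, c(0, 1, 5))
#' @export
background_model <- function(a1 = 0.9, b1 = 0.05, a2 = 0.1, b2 = 2.0) {
  if (any(c(a1, a2, b1, b2) < 0) || a1 + a2 <= 0)
    abort("background needs a1, a2, b1, b2 >= 0 and a1 + a2 > 0.")
  structure(list(a1 = a1, b1 = b1, a2 = a2, b2 = b2),
            class = "saxs_background")
}

#' @rdname background_model
#' @param model A `saxs_background`.
#' @param s Momentum transfer in nm^-1 (vectorized), >= 0.
#' @export
eval_background <- function(model, s) {
  if (any(s < 0)) abort("`s` must be >= 0.")
  model$a1 * exp(-model$b1 * s) + model$a2 * exp(-model$b2 * s)
}

#' @export
print.saxs_background <- function(x, ...) {
  cat(sprintf("<saxs_background> %g*exp(-%g s) + %g*exp(-%g s)\n",
              x$a1, x$b1, x$a2, x$b2))
  invisible(x)
}

#' Analytic sphere form-factor curve
#'
#' Scattering of a homogeneous sphere of radius `R`,
#' `I(s) = I0 * (3 * (sin(sR) - sR*cos(sR)) / (sR)^3)^2`, with the limit
#' `I(0) = I0`. Serves as a built-in absolute-scale stand-in for a
#' calculated macromolecular curve, so simulations need no external
#' curve-calculation tool. The default grid mirrors the calculated-curve
#' convention used throughout the package: 5000 points on [0, 5] nm^-1.
#'
#' @param radius Sphere radius in nm.
#' @param I0 Forward-scattering intensity (absolute scale per unit
#'   concentration).
#' @param s Momentum-transfer grid in nm^-1.
#' @return A [saxs_curve()].
#' @examples
#' head(sphere_curve(radius = 3))
#' @export
sphere_curve <- function(radius = 3, I0 = 1,
                         s = seq(0, 5, length.out = 5000)) {
  if (radius <= 0 || I0 <= 0) abort("`radius` and `I0` must be > 0.")
  x <- s * radius
  f <- ifelse(x < 1e-4,
              1 - x^2 / 10,             # series limit of 3*(sin x - x cos x)/x^3
              3 * (sin(x) - x * cos(x)) / pmax(x, 1e-300)^3)
  saxs_curve(s, I0 * f^2)
}

# linear interpolation of a curve onto s: constant below the first grid point
# (the beamstop hides that region anyway), zero above the last (no invented
# high-angle intensity)
interp_intensity <- function(curve, s) {
  out <- approx(curve$s, curve$I, xout = s, rule = 2)$y
  out[s > curve$s[length(curve$s)]] <- 0
  out[s < 0] <- NA_real_
  out
}

#' Effective intensity seen by the virtual detector
#'
#' `I_eff(s) = c * I_sample(s) + I_bg(s)`. Concentration 0 simulates pure
#' background. The sample curve is linearly interpolated on its grid,
#' extrapolated as a constant below its first point and as zero above its
#' last. The background is either a [background_model()] or a measured /
#' calculated background [saxs_curve()] on absolute scale.
#'
#' @param s Momentum transfer in nm^-1 (vectorized).
#' @param sample A [saxs_curve()] per unit concentration, or `NULL` for
#'   background only.
#' @param background A [background_model()] or [saxs_curve()].
#' @param concentration Sample concentration in mg/ml, >= 0.
#' @return Intensity at `s` (absolute scale).
#' @export
effective_intensity <- function(s, sample = NULL,
                                background = background_model(),
                                concentration = 0) {
  if (concentration < 0) abort("`concentration` must be >= 0.")
  if (concentration > 0 && is.null(sample))
    abort("`concentration` > 0 requires a sample curve.")
  bg <- if (inherits(background, "saxs_background")) eval_background(background, s)
        else if (inherits(background, "saxs_curve")) interp_intensity(background, s)
        else abort("`background` must be a background_model() or saxs_curve().")
  smp <- if (!is.null(sample) && concentration > 0)
    concentration * interp_intensity(sample, s)
  else 0
  smp + bg
}
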