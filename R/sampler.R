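#' Draw the total event count of an exposure
#'
#' Photon counting is a Poisson process, so the total number of generated
#' events of a frame is Poisson with mean `flux * exposure * kappa`.
#' The dimensionless rate factor `kappa` scales the pure-background rate for
#' the presence of sample scattering (see [simulate_image()]); `kappa = 1`
#' for background only.
#'
#' @param flux Events per second.
#' @param exposure Seconds.
#' @param kappa Dimensionless rate factor, >= 0.
#' @return A single integer draw.
#' @export
draw_event_count <- function(flux, exposure, kappa = 1) {
  mean <- flux * exposure * kappa
  if (!is.finite(mean) || mean < 0) abort("event-count mean must be finite and >= 0.")
  rpois(1L, mean)
}

#' Sample photon events in polar coordinates
#'
#' Isotropic scattering has no preferred direction, so the angle is uniform
#' on [-pi, pi); the radius is drawn by applying the quantile function of
#' the radial distribution to a uniform variate on [0, 1]. Each event
#' consumes two uniform draws, radius first, then angle -- the documented
#' RNG order shared with the compiled sampler.
#'
#' @param n Number of events, >= 0.
#' @param dist A [radial_distribution()].
#' @return A tibble with columns `r` (m) and `phi` (rad).
#' @export
sample_events <- function(n, dist) {
  n <- as.integer(n)
  if (n < 0) abort("`n` must be >= 0.")
  if (n == 0L) return(tibble(r = numeric(), phi = numeric()))
  v <- runif(2L * n)
  u_r <- v[seq.int(1L, 2L * n, by = 2L)]
  u_phi <- v[seq.int(2L, 2L * n, by = 2L)]
  tibble(r = radial_quantile(dist, u_r), phi = -pi + 2 * pi * u_phi)
}

new_detector_image <- function(counts, geometry, n_generated, n_recorded,
                               concentration = 0, seed = NA,
                               scale = NA_real_) {
  structure(list(counts = counts, geometry = geometry,
                 n_generated = n_generated, n_recorded = n_recorded,
                 concentration = concentration, seed = seed, scale = scale),
            class = "detector_image")
}

#' @export
print.detector_image <- function(x, ...) {
  cat(sprintf(
    "<detector_image> %s (%d x %d px): %s of %s events recorded, %g s exposure\n",
    x$geometry$detector$name, nrow(x$counts), ncol(x$counts),
    format(x$n_recorded, big.mark = ","), format(x$n_generated, big.mark = ","),
    x$geometry$exposure))
  invisible(x)
}

#' Accumulate polar events onto the detector pixel grid
#'
#' Maps each event to Cartesian coordinates
#' `(x, y) = beam + (r / pixel_size) * (cos(phi), sin(phi))` and increments
#' the single containing pixel (point-spread function of one pixel; the
#' containing pixel of a continuous coordinate is its nearest integer index).
#' Events falling off the grid or into an insensitive module gap are
#' discarded and appear only in `n_generated - n_recorded`.
#'
#' This is the reference R implementation; [simulate_image()] uses a
#' compiled equivalent that consumes the identical RNG stream.
#'
#' @param events Tibble with columns `r` and `phi` from [sample_events()].
#' @param geometry A [saxs_geometry()].
#' @return A `detector_image`.
#' @export
accumulate_image <- function(events, geometry) {
  det <- geometry$detector
  x <- geometry$beam[1] + (events$r / det$pixel_size) * cos(events$phi)
  y <- geometry$beam[2] + (events$r / det$pixel_size) * sin(events$phi)
  i <- floor(x + 0.5)
  j <- floor(y + 0.5)
  live <- i >= 0 & i < det$n_fast & j >= 0 & j < det$n_slow
  ii <- i[live]; jj <- j[live]
  keep <- !in_gap(ii, det$module_fast, det$gap_fast) &
          !in_gap(jj, det$module_slow, det$gap_slow)
  ii <- ii[keep]; jj <- jj[keep]
  counts <- matrix(0L, det$n_fast, det$n_slow)
  if (length(ii)) {
    idx <- ii + det$n_fast * jj + 1
    tab <- tabulate(idx, nbins = det$n_fast * det$n_slow)
    counts[] <- tab
  }
  new_detector_image(counts, geometry, n_generated = nrow(events),
                     n_recorded = length(ii))
}

#' Simulate a 2D scattering image
#'
#' End-to-end simulation of one exposure: builds the effective intensity
#' `I_eff(s) = c * I_sample(s) + I_bg(s)`, tabulates its radial event
#' distribution, draws the total event count from a Poisson law with mean
#' `flux * exposure * kappa`, samples event positions by inverse-transform
#' sampling, and quantizes them onto the pixel grid.
#'
#' The rate factor `kappa` is the ratio of the annulus-weighted integrated
#' intensities, `kappa = int I_eff(s(r)) r dr / int I_bg(s(r)) r dr`, so that
#' `flux` is the expected event rate of the pure background (`kappa = 1` at
#' concentration 0) and sample scattering adds events linearly in
#' concentration.
#'
#' The returned image carries `scale`, the expected count rate per pixel per
#' second per unit absolute intensity,
#' `scale = flux * pixel_size^2 / (2 * pi * int I_bg r dr)`; multiplying an
#' absolute-scale curve by `scale` predicts the radially averaged rate, which
#' is how simulated data are validated against their input model.
#'
#' @param geometry A [saxs_geometry()] (carries exposure and flux).
#' @param sample Optional [saxs_curve()] on absolute scale per unit
#'   concentration.
#' @param background A [background_model()] or [saxs_curve()].
#' @param concentration mg/ml; 0 simulates background only.
#' @param seed Optional integer; if given, `set.seed(seed)` is applied so the
#'   image is reproducible bit for bit.
#' @param n_nodes Radius-grid resolution of the radial distribution.
#' @param engine `"cpp"` (default) or `"r"`: both consume the same RNG
#'   stream and produce identical images.
#' @return A `detector_image`.
#' @examples
#' g <- saxs_geometry(detector_model("toy", 64, 64, 172e-6),
#'                    distance = 1, beam = c(31.5, 31.5), flux = 1e4)
#' img <- simulate_image(g, seed = 1)
#' img$n_recorded
#' @export
simulate_image <- function(geometry, sample = NULL,
                           background = background_model(),
                           concentration = 0, seed = NULL,
                           n_nodes = 8192L, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (!is.null(seed)) set.seed(seed)
  ieff <- function(s) effective_intensity(s, sample = sample,
                                          background = background,
                                          concentration = concentration)
  ibg <- function(s) effective_intensity(s, background = background)
  dist <- radial_distribution(ieff, geometry, n_nodes = n_nodes)
  w_bg <- if (concentration > 0)
    weight_integral(ibg, geometry, n_nodes = n_nodes)
  else dist$weight
  kappa <- dist$weight / w_bg
  n <- draw_event_count(geometry$flux, geometry$exposure, kappa)
  det <- geometry$detector
  if (engine == "cpp") {
    res <- cpp_sample_accumulate(as.double(n), dist$r, dist$cdf,
                                 geometry$beam[1], geometry$beam[2],
                                 det$pixel_size, det$n_fast, det$n_slow,
                                 det$module_fast, det$gap_fast,
                                 det$module_slow, det$gap_slow)
    img <- new_detector_image(res$counts, geometry, n_generated = n,
                              n_recorded = res$n_recorded)
  } else {
    img <- accumulate_image(sample_events(n, dist), geometry)
  }
  img$concentration <- concentration
  img$seed <- seed %||% NA
  img$scale <- geometry$flux * det$pixel_size^2 / (2 * pi * w_bg)
  img
}
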