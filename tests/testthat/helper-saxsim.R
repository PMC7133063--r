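# shared fixture builders -- everything is generated in code at test time

`%||%` <- function(a, b) if (is.null(a)) b else a

# gapless square detector for sampling statistics
toy_detector <- function(n = 64L, pixel = 172e-6) {
  detector_model("toy", n, n, pixel)
}

# small gapped detector exercising module-gap handling
gapped_detector <- function() {
  detector_model("gapped", 64, 64, 172e-6,
                 module_fast = 30, module_slow = 30,
                 gap_fast = 4, gap_slow = 4)
}

toy_geometry <- function(n = 64L, distance = 1, exposure = 1, flux = 2e4,
                         beam = NULL, detector = toy_detector(n)) {
  beam <- beam %||% c((detector$n_fast - 1) / 2, (detector$n_slow - 1) / 2)
  saxs_geometry(detector, distance = distance, beam = beam,
                exposure = exposure, flux = flux)
}

# brute-force oracle for the outermost radial bin: enumerate all pixel centres
max_bin_brute <- function(n_fast, n_slow, beam) {
  centres <- expand.grid(i = 0:(n_fast - 1), j = 0:(n_slow - 1))
  d <- sqrt((centres$i - beam[1])^2 + (centres$j - beam[2])^2)
  as.integer(floor(max(d) + 0.5))
}

# reduced curve built directly from vectors (for stats tests)
fake_reduced <- function(I, sigma, s = seq_along(I), exposure = 1) {
  df <- tibble::tibble(bin = seq_along(I) - 1L, s = as.numeric(s),
                       I = I, sigma = sigma, npix = 1L)
  saxsim:::new_reduced_curve(df, exposure = exposure)
}

# one full simulate -> reduce -> subtract cycle on the Table-1-style setup
simulate_subtracted <- function(distance, concentration, sample, seed,
                                flux = 1e7, mask = NULL, n_nodes = 8192L) {
  g_bg <- saxs_geometry("pilatus6m", distance = distance, exposure = 10,
                        flux = flux)
  g_s <- saxs_geometry("pilatus6m", distance = distance, exposure = 1,
                       flux = flux)
  mask <- mask %||% build_mask(g_bg$detector, g_bg$beam,
                               beamstop_diameter = 3e-3)
  set.seed(seed)
  bg <- simulate_image(g_bg, n_nodes = n_nodes)
  sm <- simulate_image(g_s, sample = sample, concentration = concentration,
                       n_nodes = n_nodes)
  bred <- radial_average(bg, mask, beamstop_diameter = 3e-3)
  sred <- radial_average(sm, mask, beamstop_diameter = 3e-3)
  subtract_and_scale(sred, bred, concentration)
}
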