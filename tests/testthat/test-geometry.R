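test_that("s_of_radius follows the scattering-angle relation", {
  g <- saxs_geometry("pilatus6m", distance = 6.0)
  expect_identical(s_of_radius(0, g), 0)
  expect_error(s_of_radius(-1e-3, g), "r")

  # reference angular ranges at 0.124 nm: bin 10 and bin 2656 at each distance
  px <- 172e-6
  expected <- list(`6` = c(0.0145, 3.8497),
                   `3` = c(0.0291, 7.6499),
                   `1.5` = c(0.0581, 14.9253))
  for (D in c(6, 3, 1.5)) {
    gd <- saxs_geometry("pilatus6m", distance = D)
    got <- round(s_of_radius(c(10, 2656) * px, gd), 4)
    expect_equal(got, expected[[as.character(D)]], tolerance = 1e-12,
                 label = sprintf("range at %g m", D))
  }

  # strictly monotone
  r <- seq(0, 0.5, length.out = 1000)
  expect_true(all(diff(s_of_radius(r, g)) > 0))

  # agrees with the small-angle limit s ~ 2*pi*r/(lambda*D) as r -> 0
  r_small <- c(1e-5, 1e-4, 1e-3)
  approx_s <- 2 * pi * r_small / (0.124 * 6.0)
  expect_equal(s_of_radius(r_small, g), approx_s, tolerance = 1e-6)
})

test_that("radius_of_s inverts s_of_radius", {
  g <- saxs_geometry("pilatus6m", distance = 6.0)
  for (r in c(1e-3, 0.1, 0.456)) {
    expect_equal(radius_of_s(s_of_radius(r, g), g), r, tolerance = 1e-12)
  }
  expect_identical(radius_of_s(0, g), 0)
  expect_error(radius_of_s(-0.1, g))
  expect_error(radius_of_s(4 * pi / 0.124, g))

  # cross-check against a bisection oracle on s_of_radius
  target <- 0.0145
  oracle <- uniroot(function(r) s_of_radius(r, g) - target,
                    c(0, 1), tol = 1e-15)$root
  expect_equal(radius_of_s(target, g), oracle, tolerance = 1e-9)
  expect_equal(oracle, 10 * 172e-6, tolerance = 2e-3)  # s printed to 4 d.p.
})

test_that("build_axis spans the requested bins on the calibrated scale", {
  g <- saxs_geometry("pilatus6m", distance = 6.0)
  one <- build_axis(g, 0, 0)
  expect_identical(nrow(one), 1L)
  expect_identical(one$s, 0)

  ax <- build_axis(g, 10, 2656)
  expect_identical(nrow(ax), 2647L)
  expect_equal(round(ax$s[1], 4), 0.0145)
  expect_equal(round(ax$s[2647], 4), 3.8497)
  expect_true(all(diff(ax$s) > 0))

  # random bin windows have the contracted length
  set.seed(1)
  for (k in 1:20) {
    a <- sample(0:500, 1); b <- a + sample(0:500, 1)
    expect_identical(nrow(build_axis(g, a, b)), as.integer(b - a + 1))
  }

  # halving the distance doubles s in the small-angle regime (<= 0.1%)
  g2 <- saxs_geometry("pilatus6m", distance = 3.0)
  small <- ax$s * 0.124 / (4 * pi) < 0.01
  ratio <- s_of_radius(ax$bin[small] * 172e-6, g2) / ax$s[small]
  expect_true(all(abs(ratio - 2) < 2 * 0.001))
})

test_that("max_bin_index matches brute-force enumeration of pixel centres", {
  d3 <- detector_model("d3", 3, 3, 1e-4)
  g3 <- saxs_geometry(d3, distance = 1, beam = c(1, 1))
  expect_identical(max_bin_index(g3), 1L)  # farthest centre at sqrt(2)

  d1 <- detector_model("d1", 1, 1, 1e-4)
  expect_identical(max_bin_index(saxs_geometry(d1, 1, beam = c(0, 0))), 0L)

  set.seed(42)
  for (k in 1:25) {
    nf <- sample(1:12, 1); ns <- sample(1:12, 1)
    beam <- c(runif(1, -3, nf + 2), runif(1, -3, ns + 2))
    g <- saxs_geometry(detector_model("t", nf, ns, 1e-4), 1, beam = beam)
    expect_identical(max_bin_index(g), max_bin_brute(nf, ns, beam))
  }

  g6 <- saxs_geometry("pilatus6m", distance = 6.0)
  expect_identical(g6$beam, c(1231, 173))
  expect_identical(max_bin_index(g6), 2656L)
})

test_that("detector catalogue entries tile exactly into modules and gaps", {
  cat <- detector_catalogue()
  expect_gte(nrow(cat), 6L)
  for (k in seq_len(nrow(cat))) {
    det <- detector(cat$name[k])   # detector_model() enforces the tiling
    expect_s3_class(det, "saxs_detector")
    kf <- (det$n_fast + det$gap_fast) / (det$module_fast + det$gap_fast)
    ks <- (det$n_slow + det$gap_slow) / (det$module_slow + det$gap_slow)
    expect_identical(kf, round(kf))
    expect_identical(ks, round(ks))
  }
  expect_error(detector("nosuch"), "pilatus6m")
  expect_error(detector_model("bad", 100, 100, 1e-4, module_fast = 30,
                              gap_fast = 4), "tiling")
})

test_that("axis files round-trip with their calibration header", {
  g <- saxs_geometry("pilatus6m", distance = 1.5)
  ax <- build_axis(g, 10, 200)
  f <- withr::local_tempfile(fileext = ".txt")
  write_axis(ax, f, geometry = g)
  back <- read_axis(f)
  expect_identical(back$bin, ax$bin)
  expect_equal(back$s, ax$s, tolerance = 1e-12)
  expect_true(any(grepl("wavelength", readLines(f))))
})
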