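test_that("total event counts are Poisson with the requested mean", {
  expect_identical(draw_event_count(0, 10), 0L)
  expect_identical(draw_event_count(100, 0), 0L)
  expect_error(draw_event_count(-1, 1), "mean")

  set.seed(5); a <- draw_event_count(50, 2, 1.3)
  set.seed(5); b <- draw_event_count(50, 2, 1.3)
  expect_identical(a, b)

  set.seed(11)
  draws <- replicate(1e4, draw_event_count(10, 10))  # mean 100
  se <- sqrt(100 / 1e4)
  expect_lt(abs(mean(draws) - 100), 4 * se)
  expect_gt(var(draws) / mean(draws), 0.9)   # Poisson: variance = mean
  expect_lt(var(draws) / mean(draws), 1.1)
})

test_that("sampled event radii follow the constructed distribution", {
  g <- toy_geometry()
  expect_identical(nrow(sample_events(0, radial_distribution(
    function(s) rep(1, length(s)), g))), 0L)

  # spike distribution: nearly all mass at one radius node
  r_spike <- 0.0015
  d_spike <- radial_distribution(function(s) {
    r <- radius_of_s(s, g)
    ifelse(abs(r - r_spike) < 2e-6, 1, 0)
  }, g, r_max = 0.003, n_nodes = 3001L)
  set.seed(2)
  ev <- sample_events(2000, d_spike)
  h <- d_spike$r[2] - d_spike$r[1]
  expect_true(all(abs(ev$r - r_spike) < 4 * h))

  # Kolmogorov-Smirnov against the constructed cdf at the 1% level
  d <- radial_distribution(sphere_curve(radius = 3), g, n_nodes = 8192L)
  set.seed(9)
  n <- 1e5
  r <- sort(sample_events(n, d)$r)
  Fhat <- saxsim:::radial_cdf(d, r)
  D <- max(pmax(abs(seq_len(n) / n - Fhat), abs((seq_len(n) - 1) / n - Fhat)))
  expect_lt(D, 1.63 / sqrt(n))

  # angles are uniform on [-pi, pi): chi-squared over 36 sectors, 1% level
  set.seed(13)
  phi <- sample_events(1e5, d)$phi
  expect_true(all(phi >= -pi & phi < pi))
  obs <- tabulate(findInterval(phi, seq(-pi, pi, length.out = 37),
                               rightmost.closed = TRUE), 36)
  chi2 <- sum((obs - 1e5 / 36)^2 / (1e5 / 36))
  expect_lt(chi2, qchisq(0.99, 35))
})

test_that("events are quantized to the nearest pixel and gaps are insensitive", {
  det <- toy_detector(64)
  g <- saxs_geometry(det, 1, beam = c(32, 32), exposure = 1, flux = 1)

  # all events at r = 0 with the beam on a pixel centre
  ev0 <- tibble::tibble(r = rep(0, 25), phi = seq(-pi, pi - 0.1,
                                                  length.out = 25))
  img0 <- accumulate_image(ev0, g)
  expect_identical(img0$counts[33, 33], 25L)
  expect_identical(sum(img0$counts), 25L)

  # continuous coordinate (10.4, 20.6) belongs to pixel (10, 21)
  gb <- saxs_geometry(det, 1, beam = c(10.4, 20.6), exposure = 1, flux = 1)
  img1 <- accumulate_image(tibble::tibble(r = 0, phi = 0), gb)
  expect_identical(img1$counts[11, 22], 1L)

  # conservation: on-detector events all land; off-detector ones are counted
  d <- radial_distribution(function(s) rep(1, length(s)), g, r_max = 0.02)
  set.seed(21)
  ev <- sample_events(5000, d)
  img <- accumulate_image(ev, g)
  expect_identical(img$n_generated, 5000L)
  expect_identical(sum(img$counts), as.integer(img$n_recorded))
  expect_lt(img$n_recorded, img$n_generated)  # r_max beyond the grid corner

  # gap pixels never record
  gg <- toy_geometry(detector = gapped_detector(), flux = 5e4)
  img_g <- simulate_image(gg, seed = 3)
  expect_identical(sum(img_g$counts[saxsim:::gap_matrix(gg$detector)]), 0L)
  expect_identical(sum(img_g$counts), as.integer(img_g$n_recorded))
})

test_that("compiled and pure-R engines consume the same stream bit for bit", {
  for (det in list(toy_detector(48), gapped_detector())) {
    g <- toy_geometry(detector = det, flux = 3e4)
    a <- simulate_image(g, sample = sphere_curve(radius = 3),
                        concentration = 0.5, seed = 77, engine = "cpp")
    b <- simulate_image(g, sample = sphere_curve(radius = 3),
                        concentration = 0.5, seed = 77, engine = "r")
    expect_identical(a$counts, b$counts)
    expect_equal(a$n_recorded, b$n_recorded)
    expect_identical(a$n_generated, b$n_generated)
  }
})

test_that("simulation is seed-deterministic and seed-sensitive", {
  g <- toy_geometry(flux = 2e4)
  a <- simulate_image(g, seed = 1)
  b <- simulate_image(g, seed = 1)
  cc <- simulate_image(g, seed = 2)
  expect_identical(a$counts, b$counts)
  expect_false(identical(a$counts, cc$counts))

  # concentration 0 is exactly the background-only simulation
  d <- simulate_image(g, sample = sphere_curve(radius = 3),
                      concentration = 0, seed = 1)
  expect_identical(a$counts, d$counts)
  expect_equal(d$scale, a$scale)
})

test_that("recorded events are isotropic across quadrants", {
  g <- toy_geometry(n = 128, flux = 1e6)
  img <- simulate_image(g, seed = 123)
  q <- c(sum(img$counts[1:64, 1:64]), sum(img$counts[65:128, 1:64]),
         sum(img$counts[1:64, 65:128]), sum(img$counts[65:128, 65:128]))
  N <- sum(q)
  tol <- 4 * sqrt(N * 0.25 * 0.75)
  expect_true(all(abs(q - N / 4) < tol))
})

test_that("binned event radii match the distribution (chi-squared GOF)", {
  g <- toy_geometry(n = 256, flux = 1)
  d <- radial_distribution(sphere_curve(radius = 3), g, n_nodes = 8192L)
  set.seed(31)
  n <- 2e5
  r <- sample_events(n, d)$r
  # equal-probability bins via the quantile function
  edges <- radial_quantile(d, seq(0, 1, length.out = 41))
  obs <- tabulate(findInterval(r, edges, rightmost.closed = TRUE), 40)
  chi2 <- sum((obs - n / 40)^2 / (n / 40))
  expect_lt(chi2, qchisq(0.99, 39))
})

test_that("kappa scales the event rate linearly in concentration", {
  g <- toy_geometry(flux = 1e5)
  sph <- sphere_curve(radius = 3)
  set.seed(17)
  img0 <- simulate_image(g, sample = sph, concentration = 0)
  # at c = 0 the mean is exactly flux * exposure
  expect_lt(abs(img0$n_generated - 1e5), 5 * sqrt(1e5))

  ieff <- function(cc) function(s) effective_intensity(s, sph,
                                                       background_model(), cc)
  w0 <- saxsim:::weight_integral(ieff(0), g)
  w1 <- saxsim:::weight_integral(ieff(1), g)
  w2 <- saxsim:::weight_integral(ieff(2), g)
  expect_equal(w2 - w0, 2 * (w1 - w0), tolerance = 1e-10)
})
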