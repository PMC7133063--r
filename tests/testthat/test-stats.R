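test_that("reduced chi-squared reproduces exact tail probabilities", {
  # identical curves: statistic 0, p = 1
  x <- c(1, 2, 3, 4)
  t0 <- reduced_chi2(x, x, rep(0.1, 4))
  expect_identical(t0$statistic, 0)
  expect_identical(t0$p, 1)

  # craft residuals whose statistic is exactly the published values
  n <- 2647L
  make <- function(stat) {
    z <- rep(sqrt(stat * (n - 1) / n), n)
    reduced_chi2(z, rep(0, n), rep(1, n))
  }
  r1 <- make(1.026)
  expect_equal(r1$statistic, 1.026, tolerance = 1e-12)
  expect_equal(round(r1$p, 3), 0.172)
  r2 <- make(0.975)
  # p from the exact tail of the rounded statistic (0.8180)
  expect_equal(r2$p, pchisq(0.975 * 2646, 2646, lower.tail = FALSE),
               tolerance = 1e-9)

  expect_error(reduced_chi2(x, x, c(0.1, 0, 0.1, 0.1)), "sigma")
  expect_error(reduced_chi2(x, x[1:3], rep(1, 4)), "length")

  # normal approximation sanity: exact sf within 0.01 of
  # pnorm-upper((stat - 1) * sqrt((n-1)/2)) at n - 1 = 2646
  for (stat in c(0.95, 0.975, 1, 1.026, 1.05)) {
    p_exact <- make(stat)$p
    p_norm <- pnorm((stat - 1) * sqrt(2646 / 2), lower.tail = FALSE)
    expect_lt(abs(p_exact - p_norm), 0.01)
  }

  # tidy()/glance() expose a one-row summary
  td <- tidy(r1)
  expect_identical(nrow(td), 1L)
  expect_named(td, c("method", "statistic", "n", "df", "p.value"))
  expect_identical(glance(r1)$p.value, td$p.value)
})

test_that("Anderson-Darling case-0 statistic and p-value are exact", {
  # single observation at 0: A^2 = -1 + 2*ln 2
  t1 <- anderson_darling(0)
  expect_equal(t1$statistic, -1 + 2 * log(2), tolerance = 1e-12)

  # published tail probability at A^2 = 0.530
  expect_equal(round(ad_pvalue(0.530), 3), 0.716)
  expect_equal(round(ad_pvalue(0.530, n = 2647), 3), 0.716)

  # classical critical values (tables print the statistic to 3 decimals)
  expect_lt(abs(ad_pvalue(1.933) - 0.10), 3e-4)
  expect_lt(abs(ad_pvalue(2.492) - 0.05), 3e-4)
  expect_lt(abs(ad_pvalue(3.857) - 0.01), 3e-4)

  # invariant under permutation of the input
  set.seed(33)
  z <- rnorm(100)
  expect_identical(anderson_darling(z)$statistic,
                   anderson_darling(sample(z))$statistic)

  # extreme values go through log-CDF asymptotics without overflow
  ex <- anderson_darling(c(rnorm(10), 40, -40))
  expect_true(is.finite(ex$statistic))
  expect_true(ex$p >= 0 && ex$p <= 1)

  expect_error(anderson_darling(numeric(0)))
  expect_error(anderson_darling(c(1, NA)))
})

test_that("Monte-Carlo p-value oracle agrees with the series approximation", {
  # empirical tail of A^2 under the null at the published statistic
  set.seed(44)
  B <- 1500L; n <- 400L
  stats <- replicate(B, {
    z <- sort(rnorm(n)); i <- seq_len(n)
    -n - mean((2 * i - 1) * (pnorm(z, log.p = TRUE) +
                               pnorm(rev(z), lower.tail = FALSE, log.p = TRUE)))
  })
  mc <- mean(stats > 0.530)
  se <- sqrt(mc * (1 - mc) / B)
  expect_lt(abs(mc - ad_pvalue(0.530, n)), 4 * se)
})

test_that("both tests hold their 1% size on true-null data", {
  set.seed(55)
  B <- 1200L; n <- 600L
  rej_chi <- 0L; rej_ad <- 0L
  for (b in seq_len(B)) {
    z <- rnorm(n)
    if (reduced_chi2(z, rep(0, n), rep(1, n))$p < 0.01) rej_chi <- rej_chi + 1L
    if (ad_pvalue(-n - mean((2 * seq_len(n) - 1) *
          (pnorm(sort(z), log.p = TRUE) +
           pnorm(rev(sort(z)), lower.tail = FALSE, log.p = TRUE))), n) < 0.01)
      rej_ad <- rej_ad + 1L
  }
  expect_lt(abs(rej_chi / B - 0.01), 0.01)
  expect_lt(abs(rej_ad / B - 0.01), 0.01)
})

test_that("standardized residuals report the within-[-3,3] fraction", {
  red <- fake_reduced(I = c(1, 2, 3, 4), sigma = rep(1, 4))
  same <- standardized_residuals(red, c(1, 2, 3, 4))
  expect_true(all(same$residual == 0))
  expect_identical(attr(same, "fraction_within_3"), 1)

  shifted <- standardized_residuals(red, c(5, 2, -1, 4))  # residuals -4,0,4,0
  expect_equal(shifted$residual, c(-4, 0, 4, 0))
  expect_identical(attr(shifted, "fraction_within_3"), 0.5)

  # against a model curve: interpolation times the stored scale
  cv <- saxs_curve(c(0.5, 4.5), c(2, 2))
  attr(red, "scale") <- 3
  rc <- standardized_residuals(red, cv)
  expect_equal(rc$model, rep(6, 4))
})

test_that("pairwise comparisons cover all unordered pairs and follow chi-squared", {
  mk <- function() fake_reduced(I = rnorm(60, 10, 0.3), sigma = rep(0.3, 60))
  set.seed(66)
  expect_identical(nrow(pairwise_compare(list(mk(), mk()))), 1L)
  expect_identical(nrow(pairwise_compare(replicate(10, mk(),
                                                   simplify = FALSE))), 45L)
  expect_error(pairwise_compare(list(mk())), "two")
  bad <- fake_reduced(I = rnorm(50), sigma = rep(1, 50))
  expect_error(pairwise_compare(list(mk(), bad)), "grid")

  # distribution of (n-1) * statistic against chi-squared_{n-1}
  set.seed(67)
  frames <- replicate(20, mk(), simplify = FALSE)
  pc <- pairwise_compare(frames)
  expect_identical(nrow(pc), 190L)
  ks <- suppressWarnings(ks.test(pc$statistic * pc$df, pchisq, df = 59))
  expect_gt(ks$p.value, 0.01)
})
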