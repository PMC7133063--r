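new_test_result <- function(method, statistic, n, df, p) {
  structure(list(method = method, statistic = statistic, n = as.integer(n),
                 df = if (is.na(df)) NA_integer_ else as.integer(df),
                 p = p),
            class = "saxs_test")
}

#' @export
print.saxs_test <- function(x, ...) {
  cat(sprintf("<saxs_test> %s: statistic %.4g, n = %d%s, p = %.4g\n",
              x$method, x$statistic, x$n,
              if (is.na(x$df)) "" else sprintf(", df = %d", x$df), x$p))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.saxs_test <- function(x, ...) {
  tibble(method = x$method, statistic = x$statistic, n = x$n,
         df = x$df, p.value = x$p)
}

#' @exportS3Method generics::glance
glance.saxs_test <- function(x, ...) tidy(x)

#' Reduced chi-squared comparison
#'
#' Tests whether observed and model values differ only by their stated
#' errors: `chi2/(n-1) = sum(((obs - model)/sigma)^2) / (n - 1)`, with the
#' upper-tail p-value of the chi-squared distribution with `n - 1` degrees
#' of freedom. A value near 1 means the differences are explained by chance
#' alone; p is the probability of a result at least this extreme under that
#' null.
#'
#' @param observed,model,sigma Equal-length numeric vectors (`n >= 2`,
#'   `sigma > 0`).
#' @return A `saxs_test` (fields `statistic`, `n`, `df`, `p`); see
#'   [tidy()].
#' @examples
#' reduced_chi2(rnorm(100, 1, 0.1), rep(1, 100), rep(0.1, 100))
#' @export
reduced_chi2 <- function(observed, model, sigma) {
  n <- length(observed)
  if (n < 2L || length(model) != n || length(sigma) != n)
    abort("observed, model, sigma must share a length >= 2.")
  if (any(sigma <= 0) || any(!is.finite(sigma)))
    abort("all `sigma` must be finite and > 0.")
  x2 <- sum(((observed - model) / sigma)^2)
  df <- n - 1L
  new_test_result("reduced chi-squared", x2 / df, n, df,
                  pchisq(x2, df, lower.tail = FALSE))
}

#' Anderson-Darling test against the standard normal
#'
#' Case-0 test: the null distribution is the fully specified N(0, 1) -- no
#' parameters are estimated, because standardized residuals of a simulation
#' come with known model and known errors. With `z` sorted and `F` the
#' standard normal CDF,
#' `A^2 = -n - (1/n) * sum_i (2i - 1) * (log F(z_i) + log(1 - F(z_(n+1-i))))`.
#' Extreme values are handled through log-CDF asymptotics rather than
#' underflowing. The p-value is the upper tail of the A^2 null distribution
#' via [ad_pvalue()].
#'
#' @param values Finite numeric vector, `n >= 1`; the caller supplies
#'   already-standardized residuals.
#' @return A `saxs_test`.
#' @examples
#' anderson_darling(rnorm(100))
#' @export
anderson_darling <- function(values) {
  n <- length(values)
  if (n < 1L || any(!is.finite(values)))
    abort("`values` must be >= 1 finite numbers.")
  z <- sort(values)
  i <- seq_len(n)
  logF <- pnorm(z, log.p = TRUE)
  logS <- pnorm(z, lower.tail = FALSE, log.p = TRUE)
  a2 <- -n - mean((2 * i - 1) * (logF + rev(logS)))
  new_test_result("Anderson-Darling (case 0)", a2, n, NA, ad_pvalue(a2, n))
}

#' Upper-tail p-value of the Anderson-Darling statistic
#'
#' High-accuracy series approximation of the case-0 limiting distribution of
#' `A^2` (Marsaglia & Marsaglia 2004: `adinf` polynomials, accurate to about
#' 2e-6), with the published finite-n correction `errfix` applied for finite
#' sample sizes (it perturbs p by O(1/n), i.e. the 4th decimal already at
#' n in the hundreds).
#'
#' @param a2 Observed statistic, >= 0.
#' @param n Sample size; `Inf` gives the pure asymptotic distribution.
#' @return `P(A^2 > a2)` under the standard-normal null.
#' @examples
#' ad_pvalue(0.530)
#' @export
ad_pvalue <- function(a2, n = Inf) {
  if (a2 < 0) abort("`a2` must be >= 0.")
  if (a2 == 0) return(1)
  x <- ad_cdf_inf(a2)
  if (is.finite(n)) x <- min(max(x + ad_errfix(n, x), 0), 1)
  1 - x
}

# limiting CDF P(A_inf^2 <= z), Marsaglia & Marsaglia (2004)
ad_cdf_inf <- function(z) {
  if (z < 2) {
    z^(-0.5) * exp(-1.2337141 / z) *
      (2.00012 + (0.247105 - (0.0649821 - (0.0347962 -
        (0.011672 - 0.00168691 * z) * z) * z) * z) * z)
  } else {
    exp(-exp(1.0776 - (2.30695 - (0.43424 - (0.082433 -
      (0.008056 - 0.0003146 * z) * z) * z) * z) * z))
  }
}

# finite-n correction to the limiting CDF at level x = ad_cdf_inf(z)
ad_errfix <- function(n, x) {
  if (x >= 0.8) {
    return((-130.2137 + (745.2337 - (1705.091 - (1950.646 -
      (1116.360 - 255.7844 * x) * x) * x) * x) * x) / n)
  }
  c1 <- 0.01265 + 0.1757 / n
  if (x < c1) {
    t <- x / c1
    t <- sqrt(t) * (1 - t) * (49 * t - 102)
    t * (0.0037 / n^3 + 0.00078 / n^2 + 0.00006 / n)
  } else {
    t <- (x - c1) / (0.8 - c1)
    (-0.00022633 + (6.54034 - (14.6538 - (14.458 - (8.259 -
      1.91864 * t) * t) * t) * t) * t) * (0.04213 + 0.01365 / n) / n
  }
}

#' Standardized residuals of a reduced curve against a model curve
#'
#' `r_i = (I_i - scale * I_model(s_i)) / sigma_i`. If model and errors are
#' correct the residuals are standard normal, so in a well-behaved
#' simulation more than 99% fall within [-3, 3]; the achieved fraction is
#' attached as attribute `fraction_within_3`.
#'
#' @param sample A `reduced_curve`.
#' @param model A [saxs_curve()] on absolute scale (interpolated onto the
#'   sample grid), or a numeric vector of model rates per bin.
#' @param scale Absolute-intensity-to-rate factor; defaults to the `scale`
#'   attribute the simulation stored on the curve (1 if absent).
#' @return A `saxs_residuals` tibble: `s`, `observed`, `model`, `sigma`,
#'   `residual`.
#' @export
standardized_residuals <- function(sample, model,
                                   scale = NULL) {
  scale <- scale %||% attr(sample, "scale") %||% 1
  if (is.na(scale)) scale <- 1
  m <- if (inherits(model, "saxs_curve")) scale * interp_intensity(model, sample$s)
       else if (is.numeric(model) && length(model) == nrow(sample)) model
       else abort("`model` must be a saxs_curve or a vector matching the grid.")
  if (any(sample$sigma <= 0)) abort("all `sigma` must be > 0.")
  r <- (sample$I - m) / sample$sigma
  out <- tibble(s = sample$s, observed = sample$I, model = m,
                sigma = sample$sigma, residual = r)
  class(out) <- c("saxs_residuals", class(out))
  attr(out, "fraction_within_3") <- mean(abs(r) <= 3)
  out
}

#' Validate a simulated curve against its input model
#'
#' Runs the reduced chi-squared comparison and the case-0 Anderson-Darling
#' normality test on the standardized residuals, the two checks under which
#' simulated data should be indistinguishable from the model up to noise.
#'
#' @inheritParams standardized_residuals
#' @return A tibble with one row per test: `method`, `statistic`, `n`, `df`,
#'   `p.value`, plus the residual fraction within [-3, 3] as attribute
#'   `fraction_within_3`.
#' @export
validate_simulation <- function(sample, model, scale = NULL) {
  res <- standardized_residuals(sample, model, scale = scale)
  chi <- reduced_chi2(res$observed, res$model, res$sigma)
  ad <- anderson_darling(res$residual)
  out <- dplyr::bind_rows(tidy(chi), tidy(ad))
  attr(out, "fraction_within_3") <- attr(res, "fraction_within_3")
  out
}

#' Pairwise reduced chi-squared comparison of frames
#'
#' Compares every unordered pair of reduced frames on a common grid with the
#' reduced chi-squared test, using the combined variance
#' `sigma^2 = sigma_1^2 + sigma_2^2` per bin. For `m` frames this yields
#' `m * (m - 1) / 2` results; for independent identical frames the
#' statistics follow the chi-squared distribution with `n - 1` degrees of
#' freedom (divided by `n - 1`).
#'
#' @param frames List of at least two `reduced_curve`s on a common grid.
#' @return A tibble with columns `frame1`, `frame2`, `statistic`, `n`, `df`,
#'   `p.value`.
#' @export
pairwise_compare <- function(frames) {
  m <- length(frames)
  if (m < 2L) abort("need at least two frames.")
  s0 <- frames[[1]]$s
  for (f in frames)
    if (length(f$s) != length(s0) || any(abs(f$s - s0) > 1e-9 * pmax(s0, 1e-12)))
      abort("frames are not on a common grid.")
  pairs <- utils::combn(m, 2L)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- frames[[pairs[1, k]]]; b <- frames[[pairs[2, k]]]
    sig <- sqrt(a$sigma^2 + b$sigma^2)
    r <- reduced_chi2(a$I, b$I, sig)
    tibble(frame1 = pairs[1, k], frame2 = pairs[2, k],
           statistic = r$statistic, n = r$n, df = r$df, p.value = r$p)
  })
}
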