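#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_raster
#'   geom_errorbar geom_hline scale_y_log10 scale_fill_viridis_c labs
#'   theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot a scattering curve
#'
#' Intensity against momentum transfer on a logarithmic intensity scale.
#'
#' @param object A [saxs_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.saxs_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$s, y = .data$I)) +
    geom_line() +
    scale_y_log10() +
    labs(x = expression(s ~ (nm^-1)), y = "I(s)") +
    theme_minimal()
}

#' Plot a reduced curve with error bars
#'
#' @param object A `reduced_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.reduced_curve <- function(object, ...) {
  df <- dplyr::filter(as_tibble(object), .data$I > 0)
  ggplot(df, aes(x = .data$s, y = .data$I)) +
    geom_errorbar(aes(ymin = pmax(.data$I - .data$sigma, .Machine$double.xmin),
                      ymax = .data$I + .data$sigma),
                  colour = "grey70", width = 0) +
    geom_point(size = 0.3) +
    scale_y_log10() +
    labs(x = expression(s ~ (nm^-1)), y = "I (counts / pixel / s)") +
    theme_minimal()
}

#' Plot standardized residuals
#'
#' Residuals against momentum transfer with the +-3 band that should contain
#' more than 99% of points for a faithful simulation.
#'
#' @param object A `saxs_residuals` tibble from [standardized_residuals()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.saxs_residuals <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$s, y = .data$residual)) +
    geom_hline(yintercept = c(-3, 0, 3), linetype = c("dashed", "solid",
                                                      "dashed"),
               colour = "grey50") +
    geom_point(size = 0.3) +
    labs(x = expression(s ~ (nm^-1)), y = "standardized residual") +
    theme_minimal()
}

#' Plot a detector image
#'
#' Counts on a log1p colour scale; large detectors are block-averaged down
#' to roughly `max_dim` pixels per axis before plotting.
#'
#' @param object A `detector_image`.
#' @param max_dim Target plotting resolution per axis.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.detector_image <- function(object, max_dim = 512L, ...) {
  m <- object$counts
  f <- max(1L, ceiling(max(dim(m)) / max_dim))
  if (f > 1L) {
    nf <- (nrow(m) %/% f) * f
    ns <- (ncol(m) %/% f) * f
    m <- m[seq_len(nf), seq_len(ns)]
    m <- rowsum(m, rep(seq_len(nf %/% f), each = f))
    m <- t(rowsum(t(m), rep(seq_len(ns %/% f), each = f)))
  }
  df <- tibble(fast = rep(seq_len(nrow(m)) - 1L, ncol(m)) * f,
               slow = rep(seq_len(ncol(m)) - 1L, each = nrow(m)) * f,
               counts = as.vector(m))
  ggplot(df, aes(x = .data$fast, y = .data$slow, fill = log1p(.data$counts))) +
    geom_raster() +
    scale_fill_viridis_c(name = "log(1 + counts)") +
    labs(x = "fast (px)", y = "slow (px)") +
    theme_minimal()
}

#' @importFrom rlang .data
NULL
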