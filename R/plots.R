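#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   facet_wrap labs scale_y_log10 theme_minimal
#' @export
ggplot2::autoplot

#' Plot a global decay fit
#'
#' Log-scale counts with the fitted reconvolved curves overlaid, one facet per
#' wavelength (subsampled to at most `max_traces` facets).
#'
#' @param object A `decay_fit`.
#' @param max_traces Maximum number of wavelength facets (default 6).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.decay_fit <- function(object, max_traces = 6, ...) {
  d <- object$fitted
  wls <- unique(d$wavelength_nm)
  if (length(wls) > max_traces) {
    keep <- wls[round(seq(1, length(wls), length.out = max_traces))]
    d <- d[d$wavelength_nm %in% keep, ]
  }
  t_ns <- d$channel * object$channel_width
  ggplot(d, aes(x = .data$channel * object$channel_width)) +
    geom_point(aes(y = pmax(.data$counts, 0.5)), size = 0.3, alpha = 0.4) +
    geom_line(aes(y = pmax(.data$fitted, 0.5)), color = "red") +
    scale_y_log10() +
    facet_wrap(~wavelength_nm, labeller = "label_both") +
    labs(x = "time (ns)", y = "counts") +
    theme_minimal()
}

#' Plot decay-associated spectra
#'
#' Component spectra (intensity vs wavelength), one line per lifetime
#' component.
#'
#' @param object A `das` object from [decay_associated_spectra()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.das <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$wavelength_nm, y = .data$intensity,
             color = factor(.data$component))) +
    geom_line() + geom_point(size = 1) +
    labs(x = "wavelength (nm)", y = "intensity (a.u.)",
         color = "component") +
    theme_minimal()
}

#' Plot a transition-curve fit
#'
#' Data points with the fitted double-Boltzmann curve.
#'
#' @param object A `transition_fit`.
#' @param n_grid Grid points for the fitted curve (default 200).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.transition_fit <- function(object, n_grid = 200, ...) {
  p <- ggplot(object$curve, aes(x = .data$urea_M, y = .data$signal)) +
    geom_point() +
    labs(x = "urea (M)", y = "signal") +
    theme_minimal()
  if (object$converged) {
    est <- stats::setNames(object$params$estimate, object$params$term)
    u <- seq(min(object$curve$urea_M), max(object$curve$urea_M),
             length.out = n_grid)
    if (object$n_transitions == 2) {
      y <- double_boltzmann(u, est["y0"], est["A"], est["p"], est["c1"],
                            est["c2"], est["k1"], est["k2"])
    } else {
      y <- double_boltzmann(u, est["y0"], est["A"], 1, est["c1"],
                            est["c1"] + 1, est["k1"], est["k1"])
    }
    p <- p + geom_line(data = tibble(urea_M = u, signal = y), color = "red")
  }
  p
}

#' Plot an inter-tryptophan distance distribution
#'
#' Histogram of per-frame indole-indole center distances.
#'
#' @param object A `distance_distribution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.distance_distribution <- function(object, ...) {
  ggplot(object$histogram,
         aes(x = .data$mid, y = .data$count)) +
    geom_col(width = object$bin_width) +
    labs(x = "distance (Å)", y = "frames") +
    theme_minimal()
}
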