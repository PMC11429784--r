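# ggplot2 views of the main result types.

#' Plot a flux sweep
#'
#' Flux magnitude against axial offset, one panel per frequency and one
#' colour per coil - the standing-wave picture a translation sweep samples.
#'
#' @param sweep Tibble from [sweep_coil_positions()].
#' @return A ggplot.
#' @export
plot_flux_sweep <- function(sweep) {
  ggplot2::ggplot(
    dplyr::mutate(sweep, fmhz = sprintf("%.1f MHz", .data$frequency_hz / 1e6),
                  mag = Mod(.data$flux)),
    ggplot2::aes(x = .data$offset_m * 100, y = .data$mag,
                 colour = .data$coil_id)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~fmhz, scales = "free_y") +
    ggplot2::labs(x = "axial offset (cm)", y = "|flux| (a.u.)",
                  colour = "coil") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an extracted tone series
#'
#' Magnitude per coil over line time.
#' @param object A `bpt_series`. @param ... Unused.
#' @export
autoplot.bpt_series <- function(object, ...) {
  ggplot2::ggplot(
    dplyr::mutate(object, mag = Mod(.data$value),
                  coil = factor(.data$coil)),
    ggplot2::aes(x = .data$line_time_s, y = .data$mag,
                 colour = .data$coil)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "|tone amplitude| (a.u.)") +
    ggplot2::theme_minimal()
}

#' Plot principal-component scores
#'
#' Training scores of the first two components.
#' @param object A `bpt_pca`. @param ... Unused.
#' @export
autoplot.bpt_pca <- function(object, ...) {
  s <- tibble::tibble(pc1 = object$scores[, 1],
                      pc2 = if (ncol(object$scores) > 1)
                        object$scores[, 2] else 0)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$pc1, y = .data$pc2)) +
    ggplot2::geom_path(alpha = 0.5) +
    ggplot2::geom_point() +
    ggplot2::labs(x = sprintf("PC1 (%.0f%%)", 100 * object$explained[1]),
                  y = if (length(object$explained) > 1)
                    sprintf("PC2 (%.0f%%)", 100 * object$explained[2])
                  else "PC2") +
    ggplot2::theme_minimal()
}

#' Plot a multicoil regression fit against its target
#' @param object A `bpt_regression`. @param ... Unused.
#' @export
autoplot.bpt_regression <- function(object, ...) {
  d <- tibble::tibble(index = seq_along(object$target),
                      target = object$target, fitted = object$fitted)
  d <- tidyr::pivot_longer(d, c("target", "fitted"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$index, y = .data$value,
                                  colour = .data$name)) +
    ggplot2::geom_line() +
    ggplot2::labs(colour = NULL,
                  subtitle = sprintf("Pearson r = %.3f", object$pearson_r)) +
    ggplot2::theme_minimal()
}
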