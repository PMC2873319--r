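#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_tile geom_point
#'   scale_x_log10 scale_fill_gradient2 labs theme_minimal
NULL

#' Plot a trajectory
#'
#' Concentration time courses, one line per species.
#'
#' @param object an `sm_trajectory`.
#' @param ... unused.
#' @export
autoplot.sm_trajectory <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), -"time",
                            names_to = "species", values_to = "concentration")
  ggplot(df, aes(x = .data$time, y = .data$concentration,
                 colour = .data$species)) +
    geom_line() +
    labs(x = "time (arbitrary units)", y = "concentration",
         colour = NULL) +
    theme_minimal()
}

#' Heatmap of a scanned S surface
#'
#' Diverging fill centred on the additive critical point S = 0: blue for
#' synergism (S < 0), red for antagonism.
#'
#' @param object a `scan_result` from [scan_surface()].
#' @param ... unused.
#' @export
autoplot.scan_result <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object))
  ggplot(df, aes(x = factor(signif(.data$scale_a, 4)),
                 y = factor(signif(.data$scale_b, 4)),
                 fill = .data$s_value)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                         midpoint = 0) +
    labs(x = "scale a", y = "scale b", fill = "S") +
    theme_minimal()
}

#' Plot equal-dose S curves
#'
#' @param curves a tibble from [s_curve()], or a named list of them (one
#'   curve per structure, e.g. serial vs parallel).
#' @export
plot_s_curves <- function(curves) {
  if (is.data.frame(curves)) curves <- list(curve = curves)
  df <- dplyr::bind_rows(curves, .id = "system")
  ggplot(df, aes(x = .data$scale, y = .data$s_value,
                 colour = .data$system)) +
    geom_line() + geom_point() +
    scale_x_log10() +
    labs(x = "dose scale (both inhibitors)",
         y = "Synergism Assessment Factor S", colour = NULL) +
    theme_minimal()
}
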