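# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a radial distribution function
#'
#' @param object a [radial_profile()] tibble.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.radial_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$r_um, y = .data$g)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$g - .data$se,
                                      ymax = .data$g + .data$se),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "r (µm)", y = "g(r) (relative intensity)")
}

#' Plot a surface-relative distribution function
#'
#' @param object a [surface_profile()] tibble.
#' @param interface_um draw the interface zone at +/- this distance (um).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.surface_profile <- function(object, interface_um = 0.39, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$d_um, y = .data$g_s)) +
    ggplot2::geom_vline(xintercept = c(-interface_um, interface_um),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted", colour = "grey70") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$g_s - .data$se,
                                      ymax = .data$g_s + .data$se),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "d (µm, negative inside granule)",
                  y = expression(g[s](d)))
}

#' Plot a distribution map
#'
#' @param object a `distribution_map` from [make_maps()].
#' @param pitch pixel pitch, um/px.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.distribution_map <- function(object, pitch = 0.065, ...) {
  d <- dim(object$values)
  ctr <- (d + 1) / 2
  df <- expand.grid(y = seq_len(d[1]), x = seq_len(d[2]))
  df$v <- as.vector(object$values)
  df$x_um <- (df$x - ctr[2]) * pitch
  df$y_um <- (df$y - ctr[1]) * pitch
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_um, y = .data$y_um,
                                   fill = .data$v)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85",
                                  name = "relative\nintensity") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)")
}

#' Plot the affinity scatter with the fitted adsorption model
#'
#' @param object an `a0_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.a0_fit <- function(object, ...) {
  xg <- seq(min(object$data$lnkg), max(object$data$lnkg), length.out = 200)
  curve <- tibble::tibble(lnkg = xg,
                          lnks = surface_affinity_relation(object$a0, xg))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$lnkg, y = .data$lnks)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(data = curve, colour = "red") +
    ggplot2::labs(x = expression(ln(k[g]) == -Delta * G[g]),
                  y = expression(ln(k[s]) == -Delta * G[s]))
}

#' Plot a threshold sweep and its quality factor
#'
#' @param sweep a `threshold_sweep` from [preprocess_and_sweep()].
#' @return a ggplot.
#' @export
plot_threshold_sweep <- function(sweep) {
  df <- tidyr::pivot_longer(
    sweep$sweep, c("n_blobs", "mean_volume", "median_volume", "quality"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level, y = .data$value)) +
    ggplot2::geom_vline(xintercept = sweep$threshold, colour = "red",
                        linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "threshold (relative intensity)", y = NULL)
}
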