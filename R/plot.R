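#' Plot a contact map
#'
#' Heatmap of the TAD x TAD contact probabilities (log10 colour scale for
#' probability maps, diverging scale for difference maps).
#'
#' @param object A `flynuc_contact_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.flynuc_contact_map <- function(object, ...) {
  long <- tidy(object, upper_only = FALSE)
  long <- dplyr::bind_rows(long, tibble::tibble(
    tad_i = attr(object, "tad_id") %||% (seq_len(nrow(object)) - 1L),
    tad_j = tad_i, class_i = NA, class_j = NA, p = diag(unclass(object))))
  gg <- ggplot2::ggplot(long, ggplot2::aes(x = .data$tad_i, y = .data$tad_j,
                                           fill = .data$p)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "TAD", y = "TAD", fill = "P(contact)") +
    ggplot2::theme_minimal()
  if (identical(attr(object, "map_type"), "difference")) {
    gg + ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                       high = "red", midpoint = 0)
  } else {
    gg + ggplot2::scale_fill_viridis_c(trans = "log10",
                                       na.value = "grey90",
                                       limits = c(max(1e-4, min(long$p[long$p > 0])), 1))
  }
}

#' Plot a radial density profile
#'
#' @param object A `flynuc_radial_profile`.
#' @param ... Unused.
#' @return A ggplot with the ensemble mean and +/- SD-of-mean ribbon.
#' @export
autoplot.flynuc_radial_profile <- function(object, ...) {
  xlab <- if (isTRUE(attr(object, "relative"))) "r / R" else "r (um)"
  ggplot2::ggplot(object, ggplot2::aes(x = .data$r_mid, y = .data$density)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$density - .data$sd_mean,
                                      ymax = .data$density + .data$sd_mean),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = xlab, y = "density (um^-3)") +
    ggplot2::theme_minimal()
}

#' Plot NE-layer occupancy along the genome
#'
#' Per-TAD probability to sit in the chosen envelope layer, coloured by L-TAD
#' status.
#'
#' @param object A `flynuc_layer_stats`.
#' @param layer Which layer column to show (default `"p_half_volume"`).
#' @param ... Unused.
#' @export
autoplot.flynuc_layer_stats <- function(object, layer = "p_half_volume", ...) {
  stopifnot(layer %in% names(object))
  sub <- object[!is.na(object$tad_id), ]
  ggplot2::ggplot(sub, ggplot2::aes(x = .data$tad_id, y = .data[[layer]],
                                    color = .data$is_ltad)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = "TAD", y = layer, color = "L-TAD") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot per-L-TAD NE contact probabilities
#'
#' @param object A `flynuc_mobility` report.
#' @param ... Unused.
#' @export
autoplot.flynuc_mobility <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$tad_id,
                                       y = .data$p_contact,
                                       color = .data$epi_class)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = c(0.2, 0.85), linetype = "dashed",
                        color = "grey50") +
    ggplot2::labs(x = "L-TAD", y = "P(contact with NE)", color = "class") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
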