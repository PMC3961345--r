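#' Plot a distance-binned metric curve
#'
#' Log-x (and optionally log-y) line-and-point plot of a `metric_curve`;
#' empty bins are dropped.
#'
#' @param object A `metric_curve`.
#' @param log_y Use a log y axis (sensible for link probability).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot metric_curve
#' @export
autoplot.metric_curve <- function(object, log_y = FALSE, ...) {
  df <- object[!is.na(object$value), ]
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$value)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "distance d (km)", y = attr(object, "metric")) +
    ggplot2::theme_minimal()
  if (log_y) gg <- gg + ggplot2::scale_y_log10()
  gg
}

#' Plot a population grid
#'
#' @param object A [population_grid].
#' @param ... Unused.
#' @return A ggplot object (log1p-scaled population tiles).
#' @method autoplot population_grid
#' @export
autoplot.population_grid <- function(object, ...) {
  df <- grid_cell_centers(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                   fill = log1p(.data$count))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "log(1 + pop)") +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Plot a Latin-square calibration scan
#'
#' Error of each design cell in the (p_v, p_c) plane (log p_c axis), with
#' the minimizing cell highlighted.
#'
#' @param object A `latin_scan` from [latin_square_scan()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot latin_scan
#' @export
autoplot.latin_scan <- function(object, ...) {
  best <- attr(object, "best")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$p_v, y = .data$p_c,
                               colour = .data$err)) +
    ggplot2::geom_point(size = 4) +
    ggplot2::geom_point(data = tibble::as_tibble(best), shape = 0,
                        size = 6, colour = "red") +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_viridis_c(name = "Err") +
    ggplot2::labs(x = "p_v", y = "p_c") +
    ggplot2::theme_minimal()
}

#' Plot mean-field series against simulation
#'
#' Clustering and reciprocity trajectories of the mean-field integrator,
#' overlaid with one or more linking-model simulations.
#'
#' @param object A `meanfield_fit`.
#' @param sim Optional `l_sim` or list of them.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot meanfield_fit
#' @export
autoplot.meanfield_fit <- function(object, sim = NULL, ...) {
  mf <- tidyr::pivot_longer(object$series, c("C", "R"),
                            names_to = "stat", values_to = "value")
  mf$source <- "mean-field"
  df <- mf
  if (!is.null(sim)) {
    sims <- if (inherits(sim, "l_sim")) list(sim) else sim
    sdf <- dplyr::bind_rows(purrr::imap(sims, function(s, i) {
      x <- tidyr::pivot_longer(
        dplyr::rename(s$series, step = "sweep"), c("C", "R"),
        names_to = "stat", values_to = "value")
      x$source <- paste0("simulation ", i)
      x[, c("step", "stat", "value", "source")]
    }))
    df <- dplyr::bind_rows(mf[, c("step", "stat", "value", "source")], sdf)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$value,
                                   colour = .data$source)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~stat, scales = "free_y") +
    ggplot2::labs(x = "sweep", y = NULL) +
    ggplot2::theme_minimal()
}
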