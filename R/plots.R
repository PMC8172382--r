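# ggplot2 autoplot methods for the package's result types.

#' Plot an empirical variogram
#'
#' Semivariance estimates against mean lag distance, point area
#' proportional to pair count, with optional fitted model curve(s).
#'
#' @param object An [empirical_variogram()].
#' @param model Optional [variogram_model()] (or named list of models) to
#'   overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.empirical_variogram <- function(object, model = NULL, ...) {
  df <- tibble::as_tibble(object)
  df <- df[df$npairs > 0, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$lag, y = .data$gamma)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$npairs), alpha = 0.8) +
    ggplot2::scale_size_area(max_size = 4, name = "pairs") +
    ggplot2::labs(
      x = "lag distance (km)",
      y = "semivariance",
      title = paste0("Empirical variogram (", attr(object, "estimator"),
                     " estimator)")) +
    ggplot2::expand_limits(y = 0) +
    ggplot2::theme_minimal()
  if (!is.null(model)) {
    models <- if (inherits(model, "variogram_model")) list(fitted = model) else model
    hh <- seq(0.01, attr(object, "max_lag_km"), length.out = 200)
    lines <- purrr::imap_dfr(models, function(m, nm) {
      tibble::tibble(lag = hh, gamma = exponential_semivariance(hh, m),
                     model = nm)
    })
    p <- p + ggplot2::geom_line(data = lines,
                                ggplot2::aes(colour = .data$model))
  }
  p
}

#' Map a kriged surface
#'
#' Tile map of the kriged prediction (or any other node-level column);
#' masked nodes, when present, are over-plotted in grey.
#'
#' @param object A [krige_grid()] result.
#' @param fill Column to map to fill (tidy-eval), default `prediction`;
#'   use `variance` for the uncertainty map or `percent` after
#'   [percent_ear_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kriging_grid <- function(object, fill = prediction, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat)) +
    ggplot2::geom_tile(ggplot2::aes(fill = {{ fill }})) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = "longitude", y = "latitude") +
    ggplot2::theme_minimal()
  if ("masked" %in% names(df) && any(df$masked)) {
    p <- p + ggplot2::geom_tile(data = df[df$masked, ], fill = "grey70")
  }
  p
}

#' Plot cross-validation standardized errors
#'
#' Histogram of the standardized squared prediction errors with the
#' observed median, the expected median under a valid model (0.455) and
#' the 95% null interval for the median.
#'
#' @param object A [cross_validate()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kriging_cv <- function(object, ...) {
  df <- object$sites
  ggplot2::ggplot(df, ggplot2::aes(x = pmin(.data$sspe, 10))) +
    ggplot2::geom_histogram(bins = 40, fill = "grey60") +
    ggplot2::geom_vline(xintercept = object$median_sspe, colour = "red") +
    ggplot2::geom_vline(xintercept = object$expected_median,
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$interval, linetype = "dotted") +
    ggplot2::labs(x = "standardized squared prediction error (truncated at 10)",
                  y = "sites",
                  title = sprintf("LOO cross-validation: median SSPE %.3f (%s)",
                                  object$median_sspe, object$verdict)) +
    ggplot2::theme_minimal()
}
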