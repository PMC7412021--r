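#' Plot a fitted retrieval curve
#'
#' Fitted characteristic-vs-GSV curve, optionally overlaid on the plot
#' observations used for fitting.
#'
#' @param object a fitted `gsv_glm` or `gsv_semiexp`.
#' @param data optional tibble of observations.
#' @param sigma,gsv column names in `data`.
#' @param gsv_max right end of the curve (m3/ha).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.gsv_glm <- function(object, data = NULL, sigma = NULL, gsv = "gsv",
                             gsv_max = 500, ...) {
  plot_fit_curve(object, data, sigma, gsv, gsv_max,
                 "Exponential GLM retrieval curve")
}

#' @rdname autoplot.gsv_glm
#' @export
autoplot.gsv_semiexp <- function(object, data = NULL, sigma = NULL,
                                 gsv = "gsv", gsv_max = 500, ...) {
  plot_fit_curve(object, data, sigma, gsv, gsv_max,
                 "Semi-exponential retrieval curve")
}

plot_fit_curve <- function(object, data, sigma, gsv, gsv_max, title) {
  grid <- tibble::tibble(gsv = seq(0, gsv_max, length.out = 200))
  grid$sigma <- predict(object, grid$gsv)
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$gsv, y = .data$sigma)) +
    ggplot2::geom_line(colour = "steelblue", linewidth = 0.8) +
    ggplot2::labs(x = "GSV (m3/ha)",
                  y = object$feature %||% "characteristic (linear power)",
                  title = title) +
    ggplot2::theme_minimal()
  if (!is.null(data)) {
    pts <- tibble::tibble(gsv = data[[gsv]],
                          sigma = data[[sigma %||% object$feature]])
    p <- p + ggplot2::geom_point(data = pts, alpha = 0.6)
  }
  p
}

#' Observed-vs-predicted scatter for LOOCV output
#'
#' @param predictions tibble from [loocv_gsv()].
#' @return A ggplot with the 1:1 line.
#' @export
plot_loocv <- function(predictions) {
  ggplot2::ggplot(predictions,
                  ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Observed GSV (m3/ha)",
                  y = "LOOCV predicted GSV (m3/ha)") +
    ggplot2::theme_minimal()
}

#' Correlation-table heat map
#'
#' Tile view of a [pearson_table()] result (sources x features), with
#' non-significant cells marked.
#'
#' @param table correlation tibble (`source`, `feature`, `gamma`,
#'   `significant`).
#' @return A ggplot.
#' @export
plot_correlation_table <- function(table) {
  table <- dplyr::mutate(
    table,
    feature = factor(.data$feature,
                     levels = intersect(feature_names(),
                                        unique(.data$feature))),
    label = paste0(sprintf("%.3f", .data$gamma),
                   ifelse(.data$significant, "", " *"))
  )
  ggplot2::ggplot(table, ggplot2::aes(x = .data$feature, y = .data$source,
                                      fill = .data$gamma)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r",
                  caption = "* not significant") +
    ggplot2::theme_minimal()
}

#' RRMSE summary across sources
#'
#' Bar view of the evaluation report: LOOCV RRMSE per source, facetted by
#' predictor, coloured by model — the single-image vs time-series
#' comparison at a glance.
#'
#' @param report report tibble from [run_gsv_pipeline()].
#' @return A ggplot.
#' @export
plot_report <- function(report) {
  report <- dplyr::mutate(
    report, source = factor(.data$source, levels = unique(.data$source)))
  ggplot2::ggplot(report, ggplot2::aes(x = .data$source, y = .data$rrmse,
                                       fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~feature) +
    ggplot2::labs(x = "acquisition source", y = "LOOCV RRMSE (%)",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Render a GSV raster
#'
#' @param raster a [power_raster()] of GSV.
#' @return A ggplot tile map (NA cells blank).
#' @export
plot_gsv_map <- function(raster) {
  d <- raster$data
  df <- tidyr::expand_grid(row = seq_len(nrow(d)), col = seq_len(ncol(d)))
  df$gsv <- d[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$gsv)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "GSV\n(m3/ha)") +
    ggplot2::theme_void()
}
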