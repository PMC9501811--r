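#' Plot the gridded environmental space and niche region
#'
#' Occurrence density as a filled raster in PCA space, the delineated
#' niche boundary, and (optionally) the regional environmental cloud.
#'
#' @param object an `env_grid`.
#' @param niche optional [delineate_niche()] result to outline.
#' @param regional_scores optional tibble with `pc1`, `pc2` to overlay.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.env_grid <- function(object, niche = NULL, regional_scores = NULL,
                              ...) {
  df <- tidyr::expand_grid(ix = seq_len(object$R), iy = seq_len(object$R)) |>
    dplyr::mutate(pc1 = object$centers_x[.data$ix],
                  pc2 = object$centers_y[.data$iy],
                  density = object$occ_density[cbind(.data$ix, .data$iy)])
  p <- ggplot2::ggplot(dplyr::filter(df, .data$density > 0),
                       ggplot2::aes(.data$pc1, .data$pc2)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$density)) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "PCA axis 1", y = "PCA axis 2",
                  fill = "occurrence\ndensity") +
    ggplot2::theme_minimal()
  if (!is.null(niche)) {
    df$in_niche <- niche$mask[cbind(df$ix, df$iy)]
    p <- p + ggplot2::geom_tile(data = dplyr::filter(df, .data$in_niche),
                                fill = NA, colour = "grey30",
                                linewidth = 0.05)
  }
  if (!is.null(regional_scores))
    p <- p + ggplot2::geom_point(data = regional_scores, size = 0.3,
                                 colour = "red", alpha = 0.5)
  p
}

#' Plot a fitted HOF response curve over its data
#'
#' @param object a `hof_fit`.
#' @param pa_series optional presence/absence series to overlay as jittered
#'   points.
#' @param show_ob draw the outer border and the `exp(-2)` threshold.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.hof_fit <- function(object, pa_series = NULL, show_ob = TRUE, ...) {
  xr <- object$x_scaling
  curve <- tibble::tibble(elevation = seq(xr[1], xr[2], length.out = 400))
  curve$p <- hof_response(object, curve$elevation)
  g <- ggplot2::ggplot(curve, ggplot2::aes(.data$elevation, .data$p)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "steelblue") +
    ggplot2::labs(x = "elevation (m a.s.l.)", y = "occurrence probability",
                  title = paste("HOF model", object$model)) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
  if (!is.null(pa_series))
    g <- g + ggplot2::geom_jitter(data = pa_series,
                                  ggplot2::aes(.data$elevation,
                                               .data$presence),
                                  width = 0, height = 0.03, size = 0.5,
                                  alpha = 0.4)
  if (show_ob) {
    ob <- outer_border(object)
    g <- g +
      ggplot2::geom_hline(yintercept = exp(-2) * object$y_max,
                          linetype = "dotted") +
      ggplot2::geom_vline(xintercept = ob$ob, linetype = "dashed",
                          colour = if (ob$censored) "orange" else "grey30")
  }
  g
}

#' Plot a predicted-UEL resampling distribution
#'
#' Histogram of the replicate outer borders with the mean and the 95%
#' percentile interval.
#'
#' @param object a `uel_prediction`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.uel_prediction <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$ob)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$mean_ob, colour = "steelblue",
                        linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = c(object$ci_low, object$ci_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "outer border (m a.s.l.)", y = "replicates") +
    ggplot2::theme_minimal()
}

#' Observed versus predicted UELs across a cohort
#'
#' One point per species with the 95% CI of its predicted limit and the
#' 1:1 line; colours give the equilibrium class.
#'
#' @param results tibble of [classify_equilibrium()] rows.
#' @return a ggplot.
#' @export
plot_obs_pred <- function(results) {
  ggplot2::ggplot(results, ggplot2::aes(.data$uel_predicted,
                                        .data$uel_observed,
                                        colour = .data$class)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0, colour = "grey30") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = c(below = "black",
                                            equilibrium = "red",
                                            above = "darkgreen",
                                            undetermined = "grey70")) +
    ggplot2::labs(x = "predicted UEL (m a.s.l.)",
                  y = "observed UEL (m a.s.l.)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Temporal change in observed limits
#'
#' Dumbbell plot of each species' first- and last-epoch observed UEL.
#'
#' @param records a [classify_change()] result.
#' @return a ggplot.
#' @export
plot_uel_change <- function(records) {
  records |>
    dplyr::mutate(species = stats::reorder(.data$species,
                                           .data$uel_first)) |>
    ggplot2::ggplot(ggplot2::aes(y = .data$species)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$uel_first,
                                       xend = .data$uel_last,
                                       yend = .data$species,
                                       colour = .data$change_class),
                          arrow = ggplot2::arrow(length = ggplot2::unit(4, "pt"))) +
    ggplot2::geom_point(ggplot2::aes(x = .data$uel_first), size = 1) +
    ggplot2::scale_colour_manual(values = c(up = "darkgreen",
                                            down = "firebrick",
                                            stable = "grey50")) +
    ggplot2::labs(x = "observed UEL (m a.s.l.)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
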