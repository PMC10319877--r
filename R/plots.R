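#' @title Plotting helpers
#' @name plots
#' @description ggplot2 views of tracks, masks and the validation curves.
NULL

#' Plot trajectories in coordinate space
#'
#' @param cohort Cohort tibble (or a single track tibble).
#' @param schools Optional school table to overlay as stars.
#' @param color Metadata column used for the trip colour (default school).
#' @return A ggplot object.
#' @export
plot_tracks <- function(cohort, schools = NULL, color = "school") {
  if (!"track" %in% names(cohort)) {
    cohort <- as_cohort(list(cohort))
  }
  pts <- tidyr::unnest(
    cohort[, c("id", "school", "mode", "track")], "track")
  p <- ggplot2::ggplot(pts, ggplot2::aes(.data$longitude, .data$latitude,
                                         group = .data$id)) +
    ggplot2::geom_path(ggplot2::aes(colour = .data[[color]]), alpha = 0.6) +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = "Longitude (deg)", y = "Latitude (deg)")
  if (!is.null(schools)) {
    p <- p + ggplot2::geom_point(
      data = schools, ggplot2::aes(.data$longitude, .data$latitude),
      inherit.aes = FALSE, shape = 8, size = 3)
  }
  p
}

#' @describeIn autoplot-curves Mean squared displacement on log-log axes.
#' @method autoplot msd_curve
#' @export
autoplot.msd_curve <- function(object, ...) {
  dat <- object[object$lag > 0, ]
  ggplot2::ggplot(dat, ggplot2::aes(.data$lag, .data$msd)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high), alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(tau ~ "(s)"),
                  y = expression(MSD ~ (m^2)))
}

#' @title Autoplot methods for validation curves
#' @name autoplot-curves
#' @param object An `msd_curve`, `vacf_curve` or `velocity_pdf` object.
#' @param ... Unused.
#' @return A ggplot object.
NULL

#' @describeIn autoplot-curves Autocorrelation of the log-normalized
#'   velocity.
#' @method autoplot vacf_curve
#' @export
autoplot.vacf_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$lag, .data$c)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high), alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = expression(tau ~ "(s)"), y = expression(C(tau)))
}

#' @describeIn autoplot-curves Pooled velocity density.
#' @method autoplot velocity_pdf
#' @export
autoplot.velocity_pdf <- function(object, ...) {
  scale <- attr(object, "scale")
  xlab <- if (identical(scale, "u")) "u = ln(v / v_m)" else "v (m/s)"
  ggplot2::ggplot(object, ggplot2::aes(.data$bin_mid, .data$density)) +
    ggplot2::geom_col(width = diff(object$bin_mid[1:2]), alpha = 0.7) +
    ggplot2::labs(x = xlab, y = "density")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
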