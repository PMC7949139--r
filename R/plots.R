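# ggplot2 diagnostics for fits and pipeline stages.

.fit_plot <- function(fit_obj, xvar, xlab, ylab, log_x = FALSE) {
  d <- tibble::tibble(xval = fit_obj$data[[xvar]],
                      obs = fit_obj$data$.response,
                      fitted = fit_obj$fitted)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$xval)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(y = .data$obs)) +
    ggplot2::labs(x = xlab, y = ylab) +
    ggplot2::theme_minimal()
  if (log_x) p <- p + ggplot2::scale_x_log10()
  p
}

#' Diagnostic plots for fitted models
#'
#' Data points with the fitted curve overlaid, on the axes conventional for
#' each experiment type (log-concentration for titrations and inhibition).
#'
#' @param object A fitted `sp_*_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot.sp_fit
NULL

#' @rdname autoplot.sp_fit
#' @export
autoplot.sp_binding_fit <- function(object, ...) {
  .fit_plot(object, "L", "total ligand", "signal", log_x = TRUE)
}

#' @rdname autoplot.sp_fit
#' @export
autoplot.sp_inhibition_fit <- function(object, ...) {
  .fit_plot(object, "I", "inhibitor", "v / Vmax", log_x = TRUE)
}

#' @rdname autoplot.sp_fit
#' @export
autoplot.sp_mm_fit <- function(object, ...) {
  .fit_plot(object, "substrate", "substrate", "velocity (per site)")
}

#' @rdname autoplot.sp_fit
#' @export
autoplot.sp_ec50_fit <- function(object, ...) {
  .fit_plot(object, "C", "effector", "OD", log_x = TRUE)
}

#' Linewidth-versus-fraction-bound plot
#'
#' The slopes of these lines, paramagnetic minus diamagnetic, carry the
#' distance information.
#'
#' @param peaks Peak tibble (as from [simulate_linewidths()]).
#' @param ctx Unused placeholder for future annotation.
#' @param kd Ligand dissociation constant for the fraction-bound axis.
#' @return A ggplot object, faceted by proton group.
#' @export
plot_broadening <- function(peaks, kd, ctx = NULL) {
  d <- dplyr::mutate(peaks, fb = fraction_bound(.data$ligand_total,
                                                .data$enzyme_sites, kd))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fb, y = .data$fwhm,
                                  colour = .data$site_id,
                                  linetype = .data$construct)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::facet_wrap(~proton_group) +
    ggplot2::labs(x = "fraction ligand bound", y = "linewidth (Hz)") +
    ggplot2::theme_minimal()
}

#' Objective values of a docked ensemble by cluster
#'
#' @param report A [cluster_poses()] report.
#' @return A ggplot object.
#' @export
plot_clusters <- function(report) {
  ggplot2::ggplot(report$assignments,
                  ggplot2::aes(x = factor(.data$cluster), y = .data$objective,
                               shape = .data$representative)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "cluster", y = "objective (kJ/mol)") +
    ggplot2::theme_minimal()
}
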