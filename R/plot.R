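#' Plot a simulated trajectory
#'
#' Faceted time courses of the six state variables: biomasses, glucose,
#' laccase activity, dye and aromatic metabolites.
#'
#' @param object a `dye_trajectory`.
#' @param vars subset of state variables to show.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot dye_trajectory
#' @export
autoplot.dye_trajectory <- function(object, vars = STATE_VARS, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("t", vars)],
    -"t", names_to = "variable", values_to = "value"
  )
  long$variable <- factor(long$variable, levels = STATE_VARS)
  cfg <- attr(object, "config")
  subtitle <- if (!is.null(cfg)) {
    sprintf("glucose %g g/l, dye %g g/l, inoculation day %g",
            cfg$alpha, cfg$beta, cfg$gamma)
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time (d)", y = NULL,
                  title = "Consortium batch simulation", subtitle = subtitle) +
    ggplot2::theme_minimal()
}

#' Plot a fitted response surface
#'
#' Filled-contour map of the predicted response over the glucose/dye design
#' box, one panel per inoculation-day slice when the basis carries gamma
#' terms.
#'
#' @param object an `rsm_model`.
#' @param n_grid grid resolution per factor.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot rsm_model
#' @export
autoplot.rsm_model <- function(object, n_grid = 61, ...) {
  grid <- surface_grid(object, n_grid = n_grid)
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$alpha, y = .data$beta,
                                          z = .data$predicted,
                                          fill = .data$predicted)) +
    ggplot2::geom_raster() +
    ggplot2::geom_contour(colour = "white", linewidth = 0.2) +
    ggplot2::scale_fill_viridis_c(name = paste0(object$response, " (d)")) +
    ggplot2::labs(x = "initial glucose (g/l)", y = "initial dye (g/l)",
                  title = paste("Response surface:", object$response)) +
    ggplot2::theme_minimal()
  if (any(object$basis$pg > 0)) {
    p <- p + ggplot2::facet_wrap(~gamma,
                                 labeller = ggplot2::label_both)
  }
  p
}
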