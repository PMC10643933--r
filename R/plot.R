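#' Plot fitted dose-response curves
#'
#' Draws the observed responses, the fitted median-effect curves with
#' pointwise confidence ribbons, and (optionally) the estimated potency
#' doses as triangle markers on each curve.
#'
#' @param object An `"me_fit"` or `"me_fit_list"` object.
#' @param ic Effect levels to mark as potency triangles, or `NULL` for
#'   none.
#' @param level Confidence level for the ribbons.
#' @param n_grid Number of grid points per curve.
#' @param ... Unused.
#' @return A ggplot object (log10 dose axis).
#' @method autoplot me_fit_list
#' @export
autoplot.me_fit_list <- function(object, ic = 50, level = 0.95,
                                 n_grid = 200, ...) {
  fits <- as_fit_list(object)
  obs <- purrr::list_rbind(purrr::map(fits, function(f) {
    tibble::tibble(agent = f$agent, dose = f$data$dose,
                   response = f$data$response)
  }))
  curves <- purrr::list_rbind(purrr::map(fits, function(f) {
    rng <- range(f$data$log10_dose)
    grid <- 10^seq(rng[1] - 0.5, rng[2] + 0.5, length.out = n_grid)
    predict_effect(f, grid, level = level)
  }))
  p <- ggplot2::ggplot(curves, ggplot2::aes(x = .data$dose)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high,
                   fill = .data$agent), alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$estimate,
                                    colour = .data$agent)) +
    ggplot2::geom_point(data = obs,
                        ggplot2::aes(y = .data$response,
                                     colour = .data$agent),
                        alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Dose (log scale)", y = "Fraction affected",
                  colour = "Agent", fill = "Agent")
  if (!is.null(ic)) {
    pots <- estimate_potency(object, x_percent = ic, level = level)
    p <- p + ggplot2::geom_point(
      data = pots,
      ggplot2::aes(x = .data$dose, y = .data$x_percent / 100,
                   colour = .data$agent),
      shape = 17, size = 3)
  }
  p
}

#' @rdname autoplot.me_fit_list
#' @method autoplot me_fit
#' @export
autoplot.me_fit <- function(object, ic = 50, level = 0.95, n_grid = 200,
                            ...) {
  fl <- structure(list(object), names = object$agent,
                  agents = object$agent, class = "me_fit_list")
  autoplot.me_fit_list(fl, ic = ic, level = level, n_grid = n_grid, ...)
}

#' Plot potency estimates with intervals
#'
#' Dot-and-interval display of ICx/ECx estimates on a log dose axis, one
#' facet per requested effect level.
#'
#' @param potencies Tibble from [estimate_potency()].
#' @return A ggplot object.
#' @export
plot_potency <- function(potencies) {
  ggplot2::ggplot(potencies,
                  ggplot2::aes(x = .data$dose, y = .data$agent)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~ x_percent,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Estimated dose (log scale)", y = "Agent")
}
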