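#' Plot a posterior distribution of the population size
#'
#' Draws the posterior probability over `n` with the MAP (solid vertical
#' line), the equal-tailed credible bounds (dashed lines) and the realized
#' tail probabilities in the subtitle.
#'
#' @param object A `discrete_posterior`.
#' @param level Credibility level for the displayed interval.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot discrete_posterior
#' @export
autoplot.discrete_posterior <- function(object, level = 0.95, ...) {
  s <- posterior_summary(object, level = level)
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$n, y = .data$prob)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::geom_vline(xintercept = s$map, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = c(s$ci_lower, s$ci_upper),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(
      x = "population size n", y = "posterior probability",
      title = sprintf("MAP = %g, %d%% CI [%g, %g]",
                      s$map, round(100 * level), s$ci_lower, s$ci_upper),
      subtitle = sprintf("tail mass below %.3g, above %.3g",
                         s$tail_lower, s$tail_upper)
    ) +
    ggplot2::theme_minimal()
}

#' @export
plot.discrete_posterior <- function(x, ...) {
  print(autoplot(x, ...))
  invisible(x)
}

#' Heatmap of a divergence scan
#'
#' @param object A `divergence_grid` from [scan_replacement_effect()] or
#'   [scan_gp_divergence()].
#' @param ... Unused.
#' @return A ggplot object showing `log10` JS divergence over the (K, R)
#'   grid.
#' @method autoplot divergence_grid
#' @export
autoplot.divergence_grid <- function(object, ...) {
  d <- as_tibble(object)
  d$log10_js <- log10(pmax(d$js_bits, 1e-300))
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$R), y = factor(.data$K),
                                  fill = .data$log10_js)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log10 JS (bits)") +
    ggplot2::labs(x = "total sampling fraction R", y = "total count K") +
    ggplot2::theme_minimal()
}

#' Survival series with fitted power law
#'
#' @param object A `power_law_fit`.
#' @param ... Unused.
#' @return A ggplot object with the estimates and the fitted curve on log10
#'   scale.
#' @method autoplot power_law_fit
#' @export
autoplot.power_law_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble(time = seq(min(d$time), max(d$time), length.out = 200))
  grid$fit <- predict(object, grid)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$map)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fit),
                       colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (days)", y = "population size estimate") +
    ggplot2::theme_minimal()
}
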