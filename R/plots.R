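#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted transgene decay curve over the data
#'
#' Observed sample frequencies per replicate, the fitted frequency curve,
#' and (by default) the binomial sampling envelope of [fit_envelope()] as a
#' grey ribbon.
#'
#' @param object A `transloss_fit` from [fit_mle()].
#' @param envelope Draw the sampling envelope (default `TRUE`; continuous
#'   fits only).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.transloss_fit <- function(object, envelope = TRUE, ...) {
  data <- dplyr::mutate(object$data,
                        frequency = .data$x_engineered / .data$n_sampled)
  xlab <- if (object$engine == "continuous") "Time (h)" else "Time"
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$time_h,
                                          y = .data$frequency))
  if (envelope && object$engine == "continuous") {
    times <- seq(min(data$time_h), max(data$time_h), length.out = 200)
    env <- fit_envelope(object, times = times,
                        n = round(stats::median(data$n_sampled)))
    p <- p +
      ggplot2::geom_ribbon(
        data = env,
        ggplot2::aes(x = .data$time_h, ymin = .data$lower, ymax = .data$upper),
        inherit.aes = FALSE, fill = "grey80"
      ) +
      ggplot2::geom_line(data = env,
                         ggplot2::aes(x = .data$time_h, y = .data$p_hat),
                         inherit.aes = FALSE, colour = "steelblue",
                         linewidth = 0.8)
  }
  p +
    ggplot2::geom_point(ggplot2::aes(colour = .data$replicate)) +
    ggplot2::labs(x = xlab, y = "Transgene frequency", colour = "Replicate") +
    ggplot2::theme_minimal()
}

#' Plot recovery-study estimates against the truth
#'
#' Two panels (mutation rate, log-log; selection coefficient, linear):
#' estimates against true values, the 1:1 line in red, and the OLS fit with
#' its 95% band in blue.
#'
#' @param object A `recovery_report` from [recovery_study()].
#' @param ... Unused.
#' @return A ggplot object (faceted).
#' @export
autoplot.recovery_report <- function(object, ...) {
  res <- object$results
  long <- dplyr::bind_rows(
    tibble::tibble(parameter = "mu", truth = res$mu_true,
                   estimate = res$mu_hat),
    tibble::tibble(parameter = "s", truth = res$s_true, estimate = res$s_hat)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$truth, y = .data$estimate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "blue",
                         fill = "grey70", linewidth = 0.7) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "True value", y = "Estimated value") +
    ggplot2::theme_minimal()
}

#' Contour plot of a likelihood surface
#'
#' @param surface The tibble returned by [likelihood_surface()].
#' @param fit Optional `transloss_fit`; its estimate is marked with a cross.
#' @return A ggplot object (mu on a log axis, filled by delta NLL above the
#'   grid minimum).
#' @export
plot_likelihood_surface <- function(surface, fit = NULL) {
  surface$dnll <- surface$nll - min(surface$nll, na.rm = TRUE)
  p <- ggplot2::ggplot(surface, ggplot2::aes(x = .data$mu, y = .data$s)) +
    ggplot2::geom_raster(ggplot2::aes(fill = pmin(.data$dnll, 50))) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$dnll),
                          breaks = c(1.92, 3, 5, 10, 25),
                          colour = "white", linewidth = 0.3) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_fill_viridis_c(name = "ΔNLL", direction = -1) +
    ggplot2::labs(x = expression(mu), y = "s") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    p <- p + ggplot2::annotate("point", x = fit$mu_hat, y = fit$s_hat,
                               shape = 4, size = 3, colour = "red")
  }
  p
}

#' Contour plot of half-life gain over reduction factors
#'
#' @param grid The tibble returned by [half_life_gain_grid()].
#' @return A ggplot object (log-log axes, filled by the t50 ratio).
#' @export
plot_gain_grid <- function(grid) {
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$k_mu, y = .data$k_s)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$ratio)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$ratio), colour = "white",
                          linewidth = 0.3) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c(name = expression(t[50] ~ ratio)) +
    ggplot2::labs(x = expression(k[mu] ~ "(mutation reduction factor)"),
                  y = expression(k[s] ~ "(selection reduction factor)")) +
    ggplot2::theme_minimal()
}
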