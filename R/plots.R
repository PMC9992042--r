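#' 1-ECDF power curves by method
#'
#' Plots, for each analysis method, one minus the empirical cumulative
#' distribution function of its per-scenario power estimates: the height at
#' threshold x is the fraction of non-null scenarios in which the method's
#' power exceeds x, and the area under the curve equals its mean power.
#'
#' @param rejection Per-scenario rejection table (see [rejection_table()]);
#'   null scenarios are dropped.
#' @return A ggplot object.
#' @export
plot_power_ecdf <- function(rejection) {
  pow <- rejection[!rejection$is_null, ]
  if (nrow(pow) == 0L) stop("no non-null scenarios to plot", call. = FALSE)
  grid <- seq(0, 1, by = 0.005)
  curves <- pow |>
    dplyr::group_by(.data$method) |>
    dplyr::reframe(threshold = grid,
                   survival = {
                     r <- .data$rate
                     vapply(grid, function(x) mean(r > x), numeric(1))
                   })
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$threshold, y = .data$survival,
                                       colour = .data$method)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::labs(x = "power threshold", y = "1 - ECDF of power estimates",
                  colour = NULL) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Type I error dot plot by method
#'
#' @param rejection Per-scenario rejection table; only null scenarios are
#'   used.
#' @param alpha Nominal level to annotate, with its Monte-Carlo band.
#' @return A ggplot object.
#' @export
plot_type1 <- function(rejection, alpha = 0.05) {
  nul <- rejection[rejection$is_null, ]
  if (nrow(nul) == 0L) stop("no null scenarios to plot", call. = FALSE)
  band <- mc_ci_band(alpha, max(nul$n_reps))
  ggplot2::ggplot(nul, ggplot2::aes(x = .data$method, y = .data$rate)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = band[1], ymax = band[2],
                      alpha = 0.15, fill = "steelblue") +
    ggplot2::geom_hline(yintercept = alpha, linetype = 2) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$rho)), size = 2) +
    ggplot2::labs(x = NULL, y = "type I error rate", colour = "rho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot method for simulation reports
#'
#' @param object A `propower_report`.
#' @param ... Unused.
#' @return A ggplot object (the 1-ECDF power curves).
#' @export
autoplot.propower_report <- function(object, ...) {
  plot_power_ecdf(object$rejection)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
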