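# Plotting -------------------------------------------------------------------

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Histogram of instantaneous diffusion coefficients with mixture overlay
#'
#' @param dinst Numeric vector of `D_inst` values or a data frame with a
#'   `d_inst` column.
#' @param fit Optional [classify_populations()] fit whose component densities
#'   are overlaid.
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_dinst_histogram <- function(dinst, fit = NULL, bins = 40) {
  if (is.data.frame(dinst)) dinst <- dinst$d_inst
  x <- log10(dinst[!is.na(dinst) & dinst > 0])
  df <- tibble::tibble(log10_d = x)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$log10_d)) +
    ggplot2::geom_histogram(
      ggplot2::aes(y = ggplot2::after_stat(density)),
      bins = bins, fill = "grey80", colour = "grey40"
    ) +
    ggplot2::labs(
      x = expression(log[10] ~ D[inst] ~ (mu * m^2 ~ s^-1)),
      y = "density"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "mobility_fit"))
    grid <- seq(min(x) - 0.5, max(x) + 0.5, length.out = 300)
    comp <- purrr::pmap(
      fit$populations,
      function(population, d_um2_s, fraction, mean_log10, sd_log10) {
        tibble::tibble(
          log10_d = grid,
          density = fraction * stats::dnorm(grid, mean_log10, sd_log10),
          population = factor(population)
        )
      }
    ) |> purrr::list_rbind()
    p <- p + ggplot2::geom_line(
      data = comp,
      ggplot2::aes(y = .data$density, colour = .data$population),
      linewidth = 0.8
    )
  }
  p
}

#' @export
autoplot.mobility_fit <- function(object, ...) {
  plot_dinst_histogram(10^object$log10_d, fit = object, ...)
}

#' Survival probability on log-log axes
#'
#' @param sp A survival tibble (possibly merged across protocols).
#' @return A ggplot object.
#' @export
plot_survival <- function(sp) {
  stopifnot(is.data.frame(sp), all(c("times_s", "sp") %in% names(sp)))
  df <- dplyr::filter(tibble::as_tibble(sp), .data$sp > 0)
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = .data$times_s, y = .data$sp,
      colour = if ("protocol" %in% names(df)) .data$protocol else NULL
    )
  ) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "time (s)", y = "survival probability", colour = "protocol"
    ) +
    ggplot2::theme_minimal()
}

#' Observed rate versus concentration with the association-constant fit
#'
#' @param object An [fit_association_constant()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.association_fit <- function(object, ...) {
  ggplot2::ggplot(
    object$data, ggplot2::aes(x = .data$c_M, y = .data$k_obs)
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      intercept = object$k_off, slope = object$k_a, colour = "red"
    ) +
    ggplot2::labs(
      x = "concentration (M)", y = expression(k[obs] ~ (s^-1))
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.association_fit
#' @param fit An [fit_association_constant()] result.
#' @export
plot_association <- function(fit) {
  autoplot.association_fit(fit)
}
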