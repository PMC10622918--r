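#' Plot a Model II fit
#'
#' Scatter of the (transformed) data with the fitted line overlaid.
#'
#' @param object A [model2_fit()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.model2_fit <- function(object, ...) {
  lab <- function(axis, tr) {
    if (tr == "log10") sprintf("log10(%s)", axis) else axis
  }
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(colour = "grey30") +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "firebrick") +
    ggplot2::labs(
      x = lab("x", object$x_transform), y = lab("y", object$y_transform),
      title = sprintf("%s fit%s", object$method,
                      if (is.na(object$segment)) "" else
                        paste0(" (", object$segment, ")")),
      subtitle = sprintf("slope %.3g, r = %.2f, permutation p = %.3g",
                         object$slope, object$r, object$p_perm)
    ) +
    ggplot2::theme_minimal()
}

#' Station responses along the productivity gradient
#'
#' Log-log scatter of a station-level response against mean primary
#' production, faceted by population, with the segmented Model II fits
#' overlaid when supplied. Mirrors the standard presentation of
#' abundance, rate, and mortality-ratio gradients in this field.
#'
#' @param stations Station table ([aggregate_stations()]) or any tibble
#'   with `pp_mean`, `population`, and the response column.
#' @param response Response column name (string).
#' @param fits Optional fits table from [segment_regressions()] (rows
#'   with `x_transform`/`y_transform == "log10"` are drawn).
#' @param floor Floor applied to nonpositive responses before log10.
#' @return A ggplot.
#' @export
plot_gradient <- function(stations, response, fits = NULL, floor = 0.01) {
  data <- stations |>
    dplyr::filter(is.finite(.data[[response]]), is.finite(.data$pp_mean)) |>
    dplyr::mutate(.y = floor_for_log(.data[[response]], floor))
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$pp_mean, y = .data$.y)) +
    ggplot2::geom_point(alpha = 0.6, colour = "grey30") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$population), scales = "free_y") +
    ggplot2::labs(x = "primary production (mg C m⁻³ d⁻¹)",
                  y = response) +
    ggplot2::theme_minimal()
  if (!is.null(fits) && nrow(fits) > 0) {
    lines <- fits |>
      dplyr::filter(.data$x_transform == "log10",
                    .data$y_transform == "log10") |>
      dplyr::mutate(
        x_lo = pmax(.data$pp_min, min(data$pp_mean)),
        x_hi = pmin(.data$pp_max, max(data$pp_mean)),
        y_lo = 10^(.data$intercept + .data$slope * log10(.data$x_lo)),
        y_hi = 10^(.data$intercept + .data$slope * log10(.data$x_hi))
      )
    p <- p + ggplot2::geom_segment(
      data = lines,
      ggplot2::aes(x = .data$x_lo, xend = .data$x_hi,
                   y = .data$y_lo, yend = .data$y_hi,
                   colour = .data$segment),
      inherit.aes = FALSE
    ) +
      ggplot2::labs(colour = "segment")
  }
  p
}

#' Bin-summary bar chart
#'
#' Mean +/- SEM of a quantity per productivity class and population,
#' the graphical counterpart of the summary produced by
#' [bin_stations()].
#'
#' @param bins Bin summary from [bin_stations()].
#' @param quantity One of `"abundance"`, `"mu"`, `"m"`, `"net"`.
#' @return A ggplot.
#' @export
plot_bin_summary <- function(bins,
                             quantity = c("m", "mu", "net", "abundance")) {
  quantity <- match.arg(quantity)
  mean_col <- paste0(quantity, "_mean")
  sem_col <- paste0(quantity, "_sem")
  data <- dplyr::filter(bins, is.finite(.data[[mean_col]]))
  ggplot2::ggplot(data, ggplot2::aes(
    x = factor(.data$pp_bin, levels = unique(bins$pp_bin)),
    y = .data[[mean_col]], fill = .data$population)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data[[mean_col]] - .data[[sem_col]],
                   ymax = .data[[mean_col]] + .data[[sem_col]]),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25) +
    ggplot2::labs(x = "primary production class", y = mean_col,
                  fill = "population") +
    ggplot2::theme_minimal()
}
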