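# ggplot2 visualisations.

#' Plot a multipass fit
#'
#' Arrival time against pass number with the fitted line
#' `t_n = t0_fit + n * tp`; per-pass means are emphasised when several
#' observations share a pass.
#'
#' @param object A `mobility_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.mobility_fit <- function(object, ...) {
  obs <- object$observations
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$n, y = .data$t_n)) +
    ggplot2::geom_abline(slope = object$tp, intercept = object$t0_fit,
                         colour = "grey40") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_point(data = object$per_pass, colour = "firebrick",
                        shape = 1, size = 3) +
    ggplot2::labs(
      x = "pass number n", y = "arrival time (ms)",
      title = sprintf("%s %s", object$compound, object$adduct),
      subtitle = sprintf("tp = %.4f ms, t0 = %.4f ms, r2 = %.6f (%s)",
                         object$tp, object$t0, object$r2, object$quality_flag)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a correction line
#'
#' Calibrant reference values against measured values with the fitted affine
#' map.
#'
#' @param object A `correction_line`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.correction_line <- function(object, ...) {
  ggplot2::ggplot(object$calibrants,
                  ggplot2::aes(x = .data$measured, y = .data$reference)) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("measured %s (ms)", object$quantity),
      y = sprintf("reference %s (ms)", object$quantity),
      title = sprintf("%s correction line", object$quantity),
      subtitle = sprintf("reference = %.5f x measured %+.5f, r2 = %.6f",
                         object$slope, object$intercept, object$r2)
    ) +
    ggplot2::theme_minimal()
}

#' Plot matched arrival times across a separation-time series
#'
#' The characteristic saw-tooth pattern of multipass acquisition: as the
#' separation time grows, the observed arrival time of a compound jumps each
#' time an additional pass is completed (wrap-around).
#'
#' @param matched Tibble from [match_mz()] over a series (columns
#'   `separation_time`, `arrival_time`, `compound`).
#' @return A ggplot.
#' @export
plot_series <- function(matched) {
  check_columns(matched, c("separation_time", "arrival_time", "compound"),
                "matched")
  ggplot2::ggplot(matched,
                  ggplot2::aes(x = .data$separation_time,
                               y = .data$arrival_time,
                               colour = .data$compound)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "separation time (ms)", y = "arrival time (ms)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
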