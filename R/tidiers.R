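# broom-style methods for fitted objects.

#' Tidy a mobility fit
#'
#' @param x A `mobility_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`t0`, `t0_fit`, `tp`).
#' @exportS3Method generics::tidy
tidy.mobility_fit <- function(x, ...) {
  tibble(
    term = c("t0", "t0_fit", "tp"),
    estimate = c(x$t0, x$t0_fit, x$tp),
    unit = "ms"
  )
}

#' @rdname tidy.mobility_fit
#' @return `glance()`: a one-row tibble with `compound`, `adduct`, `t0`,
#'   `t0_fit`, `tp`, `r2`, `n_passes_used`, `quality_flag`.
#' @exportS3Method generics::glance
glance.mobility_fit <- function(x, ...) {
  tibble(
    compound = x$compound, adduct = x$adduct,
    t0 = x$t0, t0_fit = x$t0_fit, tp = x$tp, r2 = x$r2,
    n_passes_used = x$n_passes_used, quality_flag = x$quality_flag
  )
}

#' @rdname tidy.mobility_fit
#' @return `augment()`: the fit's observations with `.fitted` and `.resid`.
#' @exportS3Method generics::augment
augment.mobility_fit <- function(x, ...) {
  obs <- x$observations
  obs$.fitted <- x$t0_fit + obs$n * x$tp
  obs$.resid <- obs$t_n - obs$.fitted
  obs
}

#' Tidy a correction line
#'
#' @param x A `correction_line`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`slope`, `intercept`).
#' @exportS3Method generics::tidy
tidy.correction_line <- function(x, ...) {
  tibble(
    term = c("slope", "intercept"),
    estimate = c(x$slope, x$intercept),
    unit = c("", "ms")
  )
}

#' @rdname tidy.correction_line
#' @return `glance()`: one row with `quantity`, `slope`, `intercept`, `r2`,
#'   `n_calibrants`, `max_residual_pct`.
#' @exportS3Method generics::glance
glance.correction_line <- function(x, ...) {
  tibble(
    quantity = x$quantity, slope = x$slope, intercept = x$intercept,
    r2 = x$r2, n_calibrants = nrow(x$calibrants),
    max_residual_pct = max(x$calibrants$residual_pct)
  )
}
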