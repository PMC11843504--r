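#' Fit a linear correction line between sessions
#'
#' Arrival-time quantities measured in one session (or on one instrument, or
#' at one traveling-wave height) are aligned to a reference session by an
#' affine map fitted on calibrant compounds:
#' `reference = slope * measured + intercept`, ordinary least squares.
#' Separate lines are fitted per quantity — periodic drift times (tp),
#' zero-pass times (t0) and multipass arrival times (tn) are never pooled,
#' as each follows its own correction line.
#'
#' Lipids behave slightly differently under the traveling wave than other
#' compound classes, so correcting lipid analytes with a line built from
#' nonlipid calibrants is discouraged (a warning is emitted when class tags
#' are supplied and disagree), though not forbidden.
#'
#' @param pairs Tibble with columns `measured` and `reference` (ms), one row
#'   per calibrant; optional `compound`/`adduct` identifiers and `class_tag`.
#' @param quantity Which quantity the line corrects: `"tp"`, `"t0"` or `"tn"`.
#' @param analyte_class Optional class tag of the analytes the line will be
#'   applied to; triggers the cross-class warning.
#'
#' @return An object of class `correction_line`: list with `quantity`,
#'   `slope`, `intercept`, `r2`, `calibrants` (the input pairs with fitted
#'   values and percent residuals `100 * |fitted - reference| / reference`).
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @export
#' @examples
#' pairs <- tibble::tibble(measured = c(10, 11, 12, 13, 14),
#'                         reference = 1.02 * c(10, 11, 12, 13, 14) - 0.5)
#' line <- fit_correction_line(pairs, "tp")
#' glance(line) # slope 1.02, intercept -0.5, r2 = 1
fit_correction_line <- function(pairs, quantity = c("tp", "t0", "tn"),
                                analyte_class = NULL) {
  quantity <- match.arg(quantity)
  pairs <- as_tibble(pairs)
  check_columns(pairs, c("measured", "reference"), "pairs")
  if (nrow(pairs) < 2) abort("At least 2 calibrant pairs are required.")
  if (length(unique(pairs$measured)) < 2) {
    abort("Degenerate calibrants: all measured values are equal.")
  }
  if (!is.null(analyte_class) && "class_tag" %in% names(pairs) &&
      all(pairs$class_tag != analyte_class)) {
    warn(sprintf(
      "Correcting %s analytes with a line built only from %s calibrants; class-matched calibrants are recommended.",
      analyte_class, paste(unique(pairs$class_tag), collapse = "/")
    ))
  }
  fit <- lm(reference ~ measured, data = pairs)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  if (!is.finite(slope) || slope == 0) abort("Degenerate correction line (slope 0).")
  pairs$fitted <- slope * pairs$measured + intercept
  pairs$residual_pct <- 100 * abs(pairs$fitted - pairs$reference) / pairs$reference
  structure(
    list(quantity = quantity, slope = slope, intercept = intercept,
         r2 = r_squared(pairs$reference, pairs$fitted),
         calibrants = pairs),
    class = "correction_line"
  )
}

#' @export
print.correction_line <- function(x, ...) {
  cat(sprintf(
    "<correction_line> %s: reference = %.6f * measured %+.6f (r2 = %.6f, %d calibrants)\n",
    x$quantity, x$slope, x$intercept, x$r2, nrow(x$calibrants)
  ))
  invisible(x)
}

#' Apply a correction line
#'
#' Elementwise `slope * value + intercept`, order preserved. With a positive
#' slope the map is strictly monotone, so corrected values keep the ranking
#' of the measured ones.
#'
#' @param line A `correction_line` from [fit_correction_line()].
#' @param values Numeric vector of measured values (ms).
#'
#' @return Corrected values (ms), same length and order.
#' @export
apply_correction <- function(line, values) {
  if (!inherits(line, "correction_line")) {
    abort("`line` must be a correction_line.")
  }
  line$slope * values + line$intercept
}

#' Mean relative error
#'
#' `MRE = mean(100 * |value - reference| / reference)`, in percent. The
#' denominator is always the reference value.
#'
#' @param values,references Equal-length numeric vectors; references `> 0`.
#'
#' @return The MRE in percent (a single number).
#' @export
#' @examples
#' mean_relative_error(117.01, 114.32) # 2.35
mean_relative_error <- function(values, references) {
  if (length(values) != length(references) || length(values) == 0) {
    abort("`values` and `references` must have equal, nonzero length.")
  }
  if (any(!is.finite(references)) || any(references <= 0)) {
    abort("All `references` must be finite and > 0.")
  }
  mean(100 * abs(values - references) / references)
}

#' Screen features by post-correction residual
#'
#' After correcting a feature list with a class-specific line, features whose
#' percent residual exceeds the threshold (strict `>`, default 0.7%) are
#' flagged out-of-class — candidates for belonging to a different compound
#' class that follows its own correction line.
#'
#' @param features Tibble with a `residual_pct` column (non-negative percent
#'   residuals); other columns are carried through.
#' @param threshold Flagging threshold in percent (default 0.7, strict `>`).
#'
#' @return `features` with an added `class_flag` column
#'   (`"in-class"`/`"out-of-class"`).
#' @export
screen_by_residual <- function(features, threshold = 0.7) {
  check_number(threshold, "threshold", positive = TRUE)
  features <- as_tibble(features)
  check_columns(features, "residual_pct", "features")
  features$class_flag <- ifelse(features$residual_pct > threshold,
                                "out-of-class", "in-class")
  features
}

#' Self-correction of a flagged feature group
#'
#' Features flagged out-of-class by [screen_by_residual()] may share their own
#' affine relation to the reference session. This fits a fresh correction line
#' within the flagged group and reports its post-correction MRE next to the
#' MRE the original (cross-class) line achieved on the same features; a much
#' lower group MRE supports the out-of-class interpretation.
#'
#' @param features Tibble of flagged features with `measured` and `reference`
#'   columns (ms); `>= 2` rows.
#' @param quantity Quantity label for the fitted line.
#' @param original_line Optional `correction_line`; when given, its MRE on
#'   this group is reported as `mre_original_pct`.
#'
#' @return A list with `line` (the group's `correction_line`),
#'   `mre_group_pct`, and `mre_original_pct` (NA when no original line given).
#' @export
group_self_correction <- function(features, quantity = c("tp", "t0", "tn"),
                                  original_line = NULL) {
  quantity <- match.arg(quantity)
  features <- as_tibble(features)
  check_columns(features, c("measured", "reference"), "features")
  if (nrow(features) < 2) {
    abort("Group self-correction needs at least 2 flagged features.")
  }
  line <- fit_correction_line(features, quantity = quantity)
  mre_group <- mean_relative_error(apply_correction(line, features$measured),
                                   features$reference)
  mre_orig <- NA_real_
  if (!is.null(original_line)) {
    mre_orig <- mean_relative_error(
      apply_correction(original_line, features$measured), features$reference
    )
  }
  list(line = line, mre_group_pct = mre_group, mre_original_pct = mre_orig)
}

#' Correct a measured mobility table against a reference table
#'
#' Joins a measured and a reference mobility-fit table on (compound, adduct),
#' fits per-quantity correction lines (tp and t0 separately) on the rows
#' whose `role` is `"calibrant"` in `refs_roles` (or on explicitly listed
#' calibrants), applies them to every compound, and reports pre- and
#' post-correction residuals.
#'
#' @param measured,reference Mobility tables (tibbles with `compound`,
#'   `adduct`, `t0`, `tp`), e.g. from [extract_mobility()] or
#'   [read_mobility_table()].
#' @param calibrants Character vector of compound names to use as calibrants,
#'   or a tibble with `compound`/`adduct`; `>= 2` shared calibrants required.
#' @param quantities Which quantities to correct (default tp and t0).
#'
#' @return A list with `lines` (named list of `correction_line`s), `table`
#'   (joined tibble with `<q>_measured`, `<q>_reference`, `<q>_corrected`,
#'   `<q>_residual_pre_pct`, `<q>_residual_post_pct` per quantity and an
#'   `is_calibrant` column), and `mre` (tibble of pre/post MRE per quantity
#'   over the non-calibrant compounds).
#' @export
correct_mobility_table <- function(measured, reference, calibrants,
                                   quantities = c("tp", "t0")) {
  check_columns(measured, c("compound", "adduct", quantities), "measured")
  check_columns(reference, c("compound", "adduct", quantities), "reference")
  joined <- dplyr::inner_join(
    measured, reference,
    by = c("compound", "adduct"), suffix = c("_measured", "_reference")
  )
  if (is.data.frame(calibrants)) {
    cal_names <- unique(calibrants$compound)
  } else {
    cal_names <- unique(calibrants)
  }
  joined$is_calibrant <- joined$compound %in% cal_names
  if (sum(joined$is_calibrant) < 2) {
    abort("Fewer than 2 shared calibrant compounds between the tables.")
  }
  lines <- list()
  for (q in quantities) {
    mcol <- paste0(q, "_measured"); rcol <- paste0(q, "_reference")
    cal <- tibble(measured = joined[[mcol]][joined$is_calibrant],
                  reference = joined[[rcol]][joined$is_calibrant])
    line <- fit_correction_line(cal, quantity = q)
    lines[[q]] <- line
    joined[[paste0(q, "_corrected")]] <- apply_correction(line, joined[[mcol]])
    joined[[paste0(q, "_residual_pre_pct")]] <-
      100 * abs(joined[[mcol]] - joined[[rcol]]) / joined[[rcol]]
    joined[[paste0(q, "_residual_post_pct")]] <-
      100 * abs(joined[[paste0(q, "_corrected")]] - joined[[rcol]]) / joined[[rcol]]
  }
  analytes <- joined[!joined$is_calibrant, , drop = FALSE]
  mre_rows <- purrr::map(quantities, function(q) {
    tibble(
      quantity = q,
      mre_pre_pct = mean(analytes[[paste0(q, "_residual_pre_pct")]]),
      mre_post_pct = mean(analytes[[paste0(q, "_residual_post_pct")]])
    )
  })
  list(lines = lines, table = as_tibble(joined),
       mre = purrr::list_rbind(mre_rows))
}
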