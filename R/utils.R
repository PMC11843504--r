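# Internal helpers shared across modules.

# Round to nearest integer, exact .5 ties broken toward the lower integer.
# Pass-number ambiguity at a tie should resolve to the smaller pass, so that
# an ion is never credited with a cycle it may not have completed.
round_half_down <- function(x) {
  ceiling(x - 0.5)
}

# Signed ppm deviation of an observed m/z from a reference m/z.
# Convention: the denominator is the reference (theoretical) m/z, the usual
# database-search convention; at <=20 ppm the two conventions differ by less
# than the tolerance granularity.
ppm_error <- function(mz, ref_mz) {
  (mz - ref_mz) / ref_mz * 1e6
}

check_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0.", name))
  if (nonneg && x < 0) abort(sprintf("`%s` must be >= 0.", name))
  invisible(x)
}

check_columns <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "`%s` is missing required column(s): %s",
      name, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# Coefficient of determination without summary.lm (which warns on exact fits).
r_squared <- function(y, fitted) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(1)
  1 - sum((y - fitted)^2) / ss_tot
}
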