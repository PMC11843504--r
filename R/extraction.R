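#' Measure zero-pass arrival times
#'
#' The zero-pass arrival time t0 of a compound is read directly from the
#' acquisition taken at the zero-pass separation time (default 0.01 ms),
#' where ions traverse the mobility region without completing a cycle.
#' Matching delegates to [match_mz()]; with several peaks in the ppm window
#' the most intense is taken.
#'
#' @param peaks Peak tibble of the zero-pass acquisition (its
#'   `separation_time` must equal `zero_pass_time`).
#' @param refs Compound reference tibble ([read_compound_refs()]).
#' @param tol_ppm m/z tolerance in ppm (default 10).
#' @param zero_pass_time Configured zero-pass separation time in ms.
#' @param on_missing `"error"` (default) to fail when a reference compound has
#'   no peak within tolerance, `"drop"` to omit it with a warning.
#'
#' @return A tibble with `compound`, `adduct`, `ref_mz`, `mz`, `t0` (ms),
#'   `intensity`.
#' @export
measure_t0 <- function(peaks, refs, tol_ppm = 10, zero_pass_time = 0.01,
                       on_missing = c("error", "drop")) {
  on_missing <- match.arg(on_missing)
  check_columns(peaks, c("mz", "arrival_time", "intensity", "separation_time"),
                "peaks")
  st <- unique(peaks$separation_time)
  if (length(st) != 1 || abs(st - zero_pass_time) > 1e-9) {
    abort(sprintf(
      "Zero-pass table must be at separation time %g ms (got %s).",
      zero_pass_time, paste(st, collapse = ", ")
    ))
  }
  refs <- validate_compound_refs(as_tibble(refs))
  matched <- match_mz(peaks, refs, tol_ppm = tol_ppm)
  missing <- dplyr::anti_join(refs, matched, by = c("compound", "adduct"))
  if (nrow(missing) > 0) {
    msg <- sprintf("t0 unavailable for: %s",
                   paste(missing$compound, missing$adduct, collapse = "; "))
    if (on_missing == "error") abort(msg) else warn(msg)
  }
  matched |>
    dplyr::transmute(.data$compound, .data$adduct, .data$ref_mz, .data$mz,
                     t0 = .data$arrival_time, .data$intensity)
}

#' Assign pass numbers to multipass arrival-time observations
#'
#' In a cyclic mobility device the observed peaks at a given separation time
#' mix pass numbers (wrap-around: faster ions overtake slower ones across
#' cycles), so the pass number n of each observation must be inferred. Given
#' the compound's zero-pass time t0, each arrival t is assigned
#' `n = round((t - t0) / tp_est)` with ties rounded to the lower pass, and
#' the cycle-time estimate `tp_est` is refined by refitting the line of t
#' against n until the assignment reaches a fixed point (at most `max_iter`
#' rounds). Observations whose residual to the final line exceeds
#' `residual_k` robust standard deviations are flagged unassigned (`n = NA`).
#'
#' The initial `tp_est` is `tp_seed` if supplied, otherwise the smallest gap
#' `t - t0` exceeding `min_tp` (gaps below `min_tp` are treated as re-sightings
#' of the zero-pass peak; single-pass drift times in this regime are several
#' milliseconds).
#'
#' @param arrivals Tibble with `separation_time` and `arrival_time` (ms) for
#'   one compound.
#' @param t0 Measured zero-pass arrival time (ms).
#' @param tp_seed Optional starting value for the cycle time (ms).
#' @param min_tp Smallest plausible cycle time (ms, default 2).
#' @param max_iter Maximum assign-refit rounds (default 50).
#' @param residual_k Outlier cutoff in robust residual SDs (default 3).
#'
#' @return `arrivals` augmented with integer `n` (NA when unassigned),
#'   `residual` (ms to the converged line) and logical
#'   `before_separation` flagging arrivals earlier than their separation time
#'   (unexpected under the acquisition model, flagged but kept).
#' @export
assign_pass_numbers <- function(arrivals, t0, tp_seed = NULL, min_tp = 2,
                                max_iter = 50, residual_k = 3) {
  check_columns(arrivals, c("separation_time", "arrival_time"), "arrivals")
  check_number(t0, "t0", nonneg = TRUE)
  t <- arrivals$arrival_time
  if (length(t) < 2 && is.null(tp_seed)) {
    abort("Cannot assign pass numbers: fewer than 2 observations and no `tp_seed`.")
  }
  if (is.null(tp_seed)) {
    gaps <- t - t0
    pos <- gaps[gaps > min_tp]
    if (length(pos) == 0) {
      abort("Cannot assign pass numbers: no arrival exceeds t0 by more than `min_tp`.")
    }
    tp_est <- min(pos)
  } else {
    check_number(tp_seed, "tp_seed", positive = TRUE)
    tp_est <- tp_seed
  }

  n <- rep(NA_integer_, length(t))
  for (iter in seq_len(max_iter)) {
    n_new <- pmax(0L, as.integer(round_half_down((t - t0) / tp_est)))
    if (identical(n_new, n)) break
    n <- n_new
    if (length(unique(n)) >= 2) {
      fit <- lm(t ~ n)
      slope <- unname(coef(fit)[2])
      if (is.finite(slope) && slope > 0) tp_est <- slope
    }
  }

  if (length(unique(n)) >= 2) {
    fit <- lm(t ~ n)
    resid <- unname(stats::residuals(fit))
  } else {
    resid <- t - (t0 + n * tp_est)
  }
  scale <- mad(resid)
  cutoff <- max(residual_k * scale, 1e-6 * tp_est)
  out <- as_tibble(arrivals)
  out$n <- n
  out$residual <- resid
  out$n[abs(resid) > cutoff] <- NA_integer_
  if (all(is.na(out$n))) abort("All observations unassignable.")
  out$before_separation <- out$arrival_time < out$separation_time
  if (any(out$before_separation)) {
    warn(sprintf("%d arrival(s) earlier than their separation time (flagged).",
                 sum(out$before_separation)))
  }
  out
}

#' Fit the multipass line t_n = t0 + n * tp
#'
#' Ordinary least squares of arrival time against pass number. When the same
#' pass is observed at several separation times, the per-pass mean enters the
#' fit. The slope is the periodic drift time tp (the cycle time of the
#' device); the intercept is a fitted estimate of t0, reported alongside the
#' directly measured value when one is supplied (the measured value is the
#' canonical t0 downstream, as it shows much lower variance).
#'
#' Quality flags: `"low_pass_count"` when fewer than `min_passes` (default 5)
#' distinct passes enter the fit; `"poor_fit"` when r^2 falls below
#' `poor_r2` or the within-pass relative spread exceeds `max_spread`
#' (bimodal or asymmetrically broadened arrival distributions, which this
#' model does not resolve).
#'
#' @param observations Tibble with integer `n` and arrival times in `t_n`
#'   (or `arrival_time`); rows with `NA` pass numbers are dropped.
#' @param t0_measured Optional directly measured zero-pass time (ms).
#' @param compound,adduct Optional identifiers carried into the result.
#' @param min_passes Distinct passes below which the fit is flagged.
#' @param poor_r2,max_spread Poor-fit thresholds (defaults 0.99 and 0.01,
#'   i.e. 1% relative within-pass spread).
#'
#' @return An object of class `mobility_fit`: a list with elements `compound`,
#'   `adduct`, `t0` (canonical), `t0_fit` (intercept), `tp` (slope, ms),
#'   `r2`, `n_passes_used`, `quality_flag`, `per_pass` (tibble of per-pass
#'   means), and `observations` (with residuals). Supports [tidy()],
#'   [glance()], [augment()] and [autoplot()].
#' @export
#' @examples
#' obs <- tibble::tibble(n = 1:5, t_n = 6 + 11 * (1:5))
#' fit <- fit_mobility(obs)
#' glance(fit) # tp = 11, intercept 6, r2 = 1
fit_mobility <- function(observations, t0_measured = NULL,
                         compound = NA_character_, adduct = NA_character_,
                         min_passes = 5, poor_r2 = 0.99, max_spread = 0.01) {
  obs <- as_tibble(observations)
  if (!"t_n" %in% names(obs) && "arrival_time" %in% names(obs)) {
    obs$t_n <- obs$arrival_time
  }
  check_columns(obs, c("n", "t_n"), "observations")
  obs <- obs[!is.na(obs$n) & is.finite(obs$t_n), , drop = FALSE]
  if (length(unique(obs$n)) < 2) {
    abort("fit_mobility needs at least 2 distinct pass numbers.")
  }
  per_pass <- obs |>
    dplyr::group_by(n = .data$n) |>
    dplyr::summarise(
      n_obs = dplyr::n(),
      spread = ifelse(dplyr::n() > 1,
                      diff(range(.data$t_n)) / mean(.data$t_n), 0),
      t_n = mean(.data$t_n),
      .groups = "drop"
    )
  fit <- lm(t_n ~ n, data = per_pass)
  tp <- unname(coef(fit)[2])
  t0_fit <- unname(coef(fit)[1])
  r2 <- r_squared(per_pass$t_n, unname(stats::fitted(fit)))
  n_passes <- nrow(per_pass)
  flag <- "ok"
  if (n_passes < min_passes) flag <- "low_pass_count"
  if (r2 < poor_r2 || max(per_pass$spread) > max_spread) flag <- "poor_fit"
  obs$residual <- obs$t_n - (t0_fit + obs$n * tp)
  structure(
    list(
      compound = compound, adduct = adduct,
      t0 = if (is.null(t0_measured)) t0_fit else t0_measured,
      t0_fit = t0_fit, tp = tp, r2 = r2,
      n_passes_used = n_passes, quality_flag = flag,
      per_pass = per_pass, observations = obs
    ),
    class = "mobility_fit"
  )
}

#' @export
print.mobility_fit <- function(x, ...) {
  cat(sprintf(
    "<mobility_fit> %s %s: t0 = %.4f ms, tp = %.4f ms (r2 = %.6f, %d passes, %s)\n",
    x$compound, x$adduct, x$t0, x$tp, x$r2, x$n_passes_used, x$quality_flag
  ))
  invisible(x)
}

#' Reconstruct a multipass arrival time from t0 and tp
#'
#' `t_n = t0 + n * tp`: the arrival time after n full cycles. Reconstruction
#' from corrected t0 and tp values is how the multipass database entries are
#' produced.
#'
#' @param fit A `mobility_fit`, a list/one-row data frame with `t0` and `tp`,
#'   or a numeric vector `c(t0, tp)`.
#' @param n Pass number(s), integer `>= 0` (vectorised).
#'
#' @return Arrival time(s) in ms.
#' @export
#' @examples
#' reconstruct_tn(c(6, 11), 9) # 105
reconstruct_tn <- function(fit, n) {
  if (any(!is.finite(n)) || any(n < 0)) abort("`n` must be >= 0.")
  if (is.numeric(fit) && length(fit) == 2) {
    t0 <- fit[[1]]; tp <- fit[[2]]
  } else {
    t0 <- fit$t0; tp <- fit$tp
  }
  check_number(t0, "t0", nonneg = TRUE)
  check_number(tp, "tp", positive = TRUE)
  t0 + n * tp
}

#' Three-measurement periodic drift time
#'
#' From three measurements — t0 (zero-pass), t1 (single pass) and tn (the
#' multipass arrival at the working separation time) — the pass number and
#' cycle time follow as `n = (tn - t0) / (t1 - t0)` rounded to the nearest
#' integer and `tp = (tn - t0) / n`. The distance `|n_raw - n|` is reported
#' as a consistency diagnostic (0 for data exactly on the multipass line).
#'
#' @param t0,t1,tn Arrival times in ms with `t1 > t0` and `tn >= t1`.
#'
#' @return A one-row tibble with `n` (integer), `tp` (ms), `n_raw`, and
#'   `consistency = |n_raw - n|`.
#' @export
#' @examples
#' three_point_tp(2, 12, 51.8) # n = 5, tp = 9.96
three_point_tp <- function(t0, t1, tn) {
  check_number(t0, "t0", nonneg = TRUE)
  check_number(t1, "t1")
  check_number(tn, "tn")
  if (t1 <= t0) abort("`t1` must exceed `t0`.")
  if (tn < t1) abort("`tn` must be >= `t1`.")
  n_raw <- (tn - t0) / (t1 - t0)
  n <- as.integer(round(n_raw))
  if (n == 0L) abort("Pass number rounds to 0; tn is indistinguishable from t0.")
  tibble(n = n, tp = (tn - t0) / n, n_raw = n_raw, consistency = abs(n_raw - n))
}

#' Extract mobility parameters for every compound in a series
#'
#' The full extraction pipeline over a separation-time series: match peaks to
#' reference compounds by m/z ([match_mz()]), read t0 from the zero-pass
#' acquisition ([measure_t0()]), assign pass numbers through the wrap-around
#' regime ([assign_pass_numbers()]) and fit the multipass line
#' ([fit_mobility()]) per compound.
#'
#' @param peaks Peak tibble spanning the whole series (`separation_time`
#'   column keys acquisitions; must include one at `zero_pass_time`).
#' @param refs Compound reference tibble.
#' @param tol_ppm m/z matching tolerance in ppm (default 10).
#' @param zero_pass_time Zero-pass separation time in ms (default 0.01).
#'
#' @return A tibble with one row per reference compound that could be fitted:
#'   `compound`, `adduct`, `mz`, `t0`, `tp`, `t0_fit`, `r2`, `n_passes`,
#'   `flag`, plus a list-column `fit` holding the `mobility_fit` objects.
#'   Columns other than `fit` match the mobility-fit CSV written by
#'   [write_mobility_table()].
#' @export
extract_mobility <- function(peaks, refs, tol_ppm = 10, zero_pass_time = 0.01) {
  refs <- validate_compound_refs(as_tibble(refs))
  zero <- peaks[abs(peaks$separation_time - zero_pass_time) <= 1e-9, ,
                drop = FALSE]
  if (nrow(zero) == 0) {
    abort(sprintf("Series has no acquisition at the zero-pass separation time (%g ms).",
                  zero_pass_time))
  }
  t0_tbl <- measure_t0(zero, refs, tol_ppm = tol_ppm,
                       zero_pass_time = zero_pass_time, on_missing = "drop")
  rest <- peaks[peaks$separation_time > zero_pass_time + 1e-9, , drop = FALSE]
  matched <- match_mz(rest, refs, tol_ppm = tol_ppm)
  rows <- purrr::pmap(
    t0_tbl[, c("compound", "adduct", "ref_mz", "t0")],
    function(compound, adduct, ref_mz, t0) {
      arr <- matched[matched$compound == compound & matched$adduct == adduct, ,
                     drop = FALSE]
      if (nrow(arr) < 2) return(NULL)
      assigned <- tryCatch(
        assign_pass_numbers(arr, t0 = t0),
        error = function(e) NULL
      )
      if (is.null(assigned)) return(NULL)
      fit <- tryCatch(
        fit_mobility(assigned, t0_measured = t0,
                     compound = compound, adduct = adduct),
        error = function(e) NULL
      )
      if (is.null(fit)) return(NULL)
      tibble(
        compound = compound, adduct = adduct, mz = ref_mz,
        t0 = fit$t0, tp = fit$tp, t0_fit = fit$t0_fit, r2 = fit$r2,
        n_passes = fit$n_passes_used, flag = fit$quality_flag,
        fit = list(fit)
      )
    }
  )
  out <- purrr::list_rbind(purrr::compact(rows))
  if (nrow(out) == 0) abort("No reference compound could be extracted from the series.")
  out
}

#' Write / read a mobility-fit table
#'
#' Serialises the tabular part of an [extract_mobility()] result (one row per
#' compound: m/z, t0, tp, r2, pass count, quality flag) as CSV.
#'
#' @param fits Tibble from [extract_mobility()] (a `fit` list-column, if
#'   present, is dropped).
#' @param path CSV path.
#' @return `path` invisibly; `read_mobility_table()` returns the tibble.
#' @export
write_mobility_table <- function(fits, path) {
  check_columns(fits, c("compound", "adduct", "mz", "t0", "tp"), "fits")
  fits <- fits[, setdiff(names(fits), "fit"), drop = FALSE]
  readr::write_csv(fits, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_mobility_table
#' @export
read_mobility_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("Mobility table not found: %s", path))
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
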