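# Simulated cIM-MS multipass acquisitions: the ground-truth oracle used to
# validate extraction, correction and annotation. The acquisition model is a
# deliberate simplification of the real ejection geometry: at separation time
# T, a compound with session values (t0', tp') produces a detectable peak for
# every pass n with 0 <= (t0' + n*tp') - T <= window.

with_seed <- function(seed, code) {
  if (is.null(seed)) abort("A `seed` is required for every stochastic call.")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' The standard separation-time schedule
#'
#' 0.01 ms (the zero-pass acquisition) followed by the multipass ladder:
#' 1-20 ms in steps of 1, 20-40 ms in steps of 2, 40-100 ms in steps of 5 and
#' 100-150 ms in steps of 10, with shared boundary points included once —
#' 48 separation times in total, strictly increasing.
#'
#' @return Numeric vector of separation times (ms).
#' @export
default_schedule <- function() {
  c(0.01, 1:20, seq(22, 40, by = 2), seq(45, 100, by = 5),
    seq(110, 150, by = 10))
}

#' Random compound set for simulations
#'
#' Draws lipid-like compounds with cycle times and zero-pass times in the
#' regime of lipid adducts on a cyclic mobility device (single-pass drift
#' times of a few to a few tens of ms).
#'
#' @param n Number of compounds.
#' @param seed RNG seed (mandatory).
#' @param tp_range,t0_range Uniform ranges for the true cycle time and
#'   zero-pass time (ms); defaults 10-14 and 5-8.
#' @param mz_range m/z range (Th), spread evenly with small jitter so
#'   compounds are unambiguous at 10 ppm.
#' @param class_tag Class label(s), recycled.
#'
#' @return Tibble with `compound`, `adduct`, `mz`, `t0_true`, `tp_true`,
#'   `base_intensity`, `class_tag`.
#' @export
sim_compounds <- function(n, seed, tp_range = c(10, 14), t0_range = c(5, 8),
                          mz_range = c(436, 786), class_tag = "lipid") {
  check_number(n, "n", positive = TRUE)
  with_seed(seed, {
    mz <- seq(mz_range[1], mz_range[2], length.out = n) +
      runif(n, -0.01, 0.01)
    tibble(
      compound = sprintf("SIM%03d", seq_len(n)),
      adduct = "[M+H]+",
      mz = mz,
      t0_true = runif(n, t0_range[1], t0_range[2]),
      tp_true = runif(n, tp_range[1], tp_range[2]),
      base_intensity = runif(n, 2e4, 1e5),
      class_tag = rep_len(class_tag, n)
    )
  })
}

#' Session drift model
#'
#' Between sessions (days, instruments, ambient temperatures, wave heights)
#' the cycle time and zero-pass time of every compound shift by affine maps
#' `tp' = tp_slope * tp + tp_intercept` and `t0' = t0_slope * t0 +
#' t0_intercept`, on top of multiplicative measurement noise with coefficient
#' of variation `noise_cv`. An optional second set of maps can be attached to
#' one compound class (`class_specific`), emulating class-dependent behaviour
#' under the traveling wave.
#'
#' @param tp_slope,tp_intercept,t0_slope,t0_intercept Affine drift maps
#'   (slopes `> 0`, intercepts in ms).
#' @param noise_cv Fractional coefficient of variation of multiplicative
#'   arrival-time noise (`>= 0`; 0.001 is a typical intraday level).
#' @param class_specific Optional list with `class_tag` and its own
#'   `tp_slope`/`tp_intercept`/`t0_slope`/`t0_intercept`.
#'
#' @return List of class `session_drift`.
#' @export
session_drift <- function(tp_slope = 1, tp_intercept = 0,
                          t0_slope = 1, t0_intercept = 0,
                          noise_cv = 0, class_specific = NULL) {
  if (tp_slope <= 0 || t0_slope <= 0) abort("Drift slopes must be > 0.")
  check_number(noise_cv, "noise_cv", nonneg = TRUE)
  structure(
    list(tp_slope = tp_slope, tp_intercept = tp_intercept,
         t0_slope = t0_slope, t0_intercept = t0_intercept,
         noise_cv = noise_cv, class_specific = class_specific),
    class = "session_drift"
  )
}

drifted_values <- function(compounds, drift) {
  tp_s <- rep(drift$tp_slope, nrow(compounds))
  tp_i <- rep(drift$tp_intercept, nrow(compounds))
  t0_s <- rep(drift$t0_slope, nrow(compounds))
  t0_i <- rep(drift$t0_intercept, nrow(compounds))
  cs <- drift$class_specific
  if (!is.null(cs)) {
    sel <- compounds$class_tag == cs$class_tag
    tp_s[sel] <- cs$tp_slope %||% drift$tp_slope
    tp_i[sel] <- cs$tp_intercept %||% drift$tp_intercept
    t0_s[sel] <- cs$t0_slope %||% drift$t0_slope
    t0_i[sel] <- cs$t0_intercept %||% drift$t0_intercept
  }
  tibble(
    t0_session = t0_s * compounds$t0_true + t0_i,
    tp_session = tp_s * compounds$tp_true + tp_i
  )
}

#' Simulate a separation-time series
#'
#' Emits, for every compound and scheduled separation time T, one peak per
#' pass n satisfying `0 <= (t0' + n * tp') - T <= window` (the acquisition
#' window), where the primed values are the session's drift-transformed t0
#' and tp. Arrival times carry multiplicative Gaussian noise with CV
#' `drift$noise_cv`; intensity decays geometrically with pass number
#' (`decay^n`, with a floor), so a detection threshold reproduces the loss of
#' high-pass signals for weak compounds.
#'
#' @param compounds Tibble from [sim_compounds()] (columns `compound`,
#'   `adduct`, `mz`, `t0_true`, `tp_true`, `base_intensity`, `class_tag`).
#' @param schedule Separation times in ms (default [default_schedule()]).
#' @param drift A [session_drift()] (default: identity, no noise).
#' @param window Acquisition window in ms (default 26.4).
#' @param seed RNG seed (mandatory).
#' @param decay Per-pass intensity decay factor (default 0.7).
#' @param intensity_floor Minimum emitted intensity (default 10 counts).
#' @param min_intensity Detection threshold: peaks below it are not emitted
#'   (default 0 = keep all).
#' @param polarity Recorded polarity tag.
#'
#' @return A list with `peaks` (peak tibble as from [read_peaklist()], rows
#'   shuffled within each acquisition in intensity order) and `truth`
#'   (tibble `compound`, `adduct`, `separation_time`, `n`, `t_true`
#'   (noiseless session arrival), `t_emitted`, plus the per-compound session
#'   values `t0_session`, `tp_session`).
#' @export
simulate_series <- function(compounds, schedule = default_schedule(),
                            drift = session_drift(), window = 26.4,
                            seed, decay = 0.7, intensity_floor = 10,
                            min_intensity = 0, polarity = "positive") {
  if (length(schedule) == 0 || any(diff(schedule) <= 0)) {
    abort("`schedule` must be non-empty and strictly increasing.")
  }
  check_number(window, "window", positive = TRUE)
  check_columns(compounds, c("compound", "adduct", "mz", "t0_true", "tp_true",
                             "base_intensity", "class_tag"), "compounds")
  sess <- drifted_values(compounds, drift)
  with_seed(seed, {
    rows <- purrr::pmap(
      cbind(compounds, sess),
      function(compound, adduct, mz, t0_true, tp_true, base_intensity,
               class_tag, t0_session, tp_session, ...) {
        per_T <- purrr::map(schedule, function(st) {
          n_lo <- max(0L, ceiling((st - t0_session) / tp_session))
          n_hi <- floor((st + window - t0_session) / tp_session)
          if (n_hi < n_lo) return(NULL)
          n <- seq.int(n_lo, n_hi)
          t_true <- t0_session + n * tp_session
          keep <- t_true - st >= 0 & t_true - st <= window
          n <- n[keep]; t_true <- t_true[keep]
          if (length(n) == 0) return(NULL)
          eps <- rnorm(length(n), 0, drift$noise_cv)
          intensity <- pmax(base_intensity * decay^n, intensity_floor)
          tibble(
            compound = compound, adduct = adduct, mz = mz,
            separation_time = st, n = n, t_true = t_true,
            t_emitted = t_true * (1 + eps), intensity = intensity,
            t0_session = t0_session, tp_session = tp_session
          )
        })
        purrr::list_rbind(purrr::compact(per_T))
      }
    )
    truth <- purrr::list_rbind(rows)
    truth <- truth[truth$intensity >= min_intensity, , drop = FALSE]
    peaks <- tibble(
      mz = truth$mz,
      arrival_time = truth$t_emitted,
      intensity = truth$intensity,
      separation_time = truth$separation_time,
      polarity = polarity,
      source_id = sprintf("sim_T%g", truth$separation_time)
    )
    ord <- order(peaks$separation_time, -peaks$intensity)
    list(peaks = peaks[ord, , drop = FALSE], truth = truth)
  })
}

#' Simulate two sessions related by a known drift
#'
#' Session A is the reference (identity maps, measurement noise only);
#' session B applies the given drift maps. The true affine maps are returned
#' for recovery tests.
#'
#' @param compounds Tibble from [sim_compounds()].
#' @param drift_a_to_b A [session_drift()] describing session B relative to
#'   the truth (session A uses identity maps with the same `noise_cv`).
#' @param seed RNG seed; the two sessions use independent draws.
#' @inheritParams simulate_series
#'
#' @return List with `session_a`, `session_b` (each as [simulate_series()]
#'   output) and `true_maps` (list of `tp = c(slope, intercept)`,
#'   `t0 = c(slope, intercept)` mapping session-B values back from truth).
#' @export
simulate_two_sessions <- function(compounds, drift_a_to_b, seed,
                                  schedule = default_schedule(),
                                  window = 26.4, min_intensity = 0) {
  identity_drift <- session_drift(noise_cv = drift_a_to_b$noise_cv)
  a <- simulate_series(compounds, schedule = schedule, drift = identity_drift,
                       window = window, seed = seed,
                       min_intensity = min_intensity)
  b <- simulate_series(compounds, schedule = schedule, drift = drift_a_to_b,
                       window = window, seed = seed + 1L,
                       min_intensity = min_intensity)
  list(
    session_a = a, session_b = b,
    true_maps = list(
      tp = c(slope = drift_a_to_b$tp_slope,
             intercept = drift_a_to_b$tp_intercept),
      t0 = c(slope = drift_a_to_b$t0_slope,
             intercept = drift_a_to_b$t0_intercept)
    )
  )
}

#' Value-level two-session drift simulation
#'
#' The lightweight counterpart of [simulate_two_sessions()]: instead of
#' emitting full peak lists, it applies the session maps and multiplicative
#' noise directly to each compound's (t0, tp) values — session A with
#' identity maps, session B with the drift maps, both with noise CV
#' `drift$noise_cv`. This isolates the correction step from extraction.
#'
#' @param compounds Tibble from [sim_compounds()].
#' @param drift A [session_drift()].
#' @param seed RNG seed (mandatory).
#'
#' @return `compounds` augmented with `t0_a`, `tp_a` (session A) and
#'   `t0_b`, `tp_b` (session B) measured values.
#' @export
simulate_session_values <- function(compounds, drift, seed) {
  check_columns(compounds, c("compound", "t0_true", "tp_true", "class_tag"),
                "compounds")
  sess <- drifted_values(compounds, drift)
  with_seed(seed, {
    n <- nrow(compounds)
    noisy <- function(x) x * (1 + rnorm(n, 0, drift$noise_cv))
    out <- as_tibble(compounds)
    out$t0_a <- noisy(compounds$t0_true)
    out$tp_a <- noisy(compounds$tp_true)
    out$t0_b <- noisy(sess$t0_session)
    out$tp_b <- noisy(sess$tp_session)
    out
  })
}
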