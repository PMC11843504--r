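#' Column-mapping dialect for peak-list files
#'
#' Vendor post-processing software exports peak lists as plain tables whose
#' column names vary. A dialect names the mass-to-charge, drift and intensity
#' columns and states whether the drift column holds arrival times in
#' milliseconds or integer drift-bin indices that must be converted with
#' [bins_to_ms()].
#'
#' @param mz,drift,intensity Column names in the file.
#' @param drift_unit Either `"bin"` (integer bin index, converted to ms with
#'   `bin_width`/`offset`) or `"ms"` (already milliseconds).
#' @param bin_width Bin width in ms. The default is the acquisition window
#'   divided by the number of drift bins (26.4 ms / 200 bins = 0.132 ms).
#' @param offset Additive offset in ms applied after bin conversion, for
#'   exports whose times are relative to the start of the acquisition window
#'   rather than to injection.
#'
#' @return A list of class `peaklist_dialect`.
#' @export
#' @examples
#' peaklist_dialect(mz = "m/z", drift = "DriftTime", drift_unit = "ms")
peaklist_dialect <- function(mz = "mz", drift = "drift", intensity = "intensity",
                             drift_unit = c("bin", "ms"),
                             bin_width = 26.4 / 200, offset = 0) {
  drift_unit <- match.arg(drift_unit)
  check_number(bin_width, "bin_width", positive = TRUE)
  check_number(offset, "offset")
  structure(
    list(mz = mz, drift = drift, intensity = intensity,
         drift_unit = drift_unit, bin_width = bin_width, offset = offset),
    class = "peaklist_dialect"
  )
}

#' Convert drift-bin indices to arrival times in milliseconds
#'
#' `arrival_time = offset + drift_bin * bin_width`. The default bin width is
#' the 26.4 ms ejection-and-acquisition window divided over 200 drift bins.
#'
#' @param drift_bin Integer bin index (vectorised), `>= 0`.
#' @param bin_width Bin width in ms, `> 0`.
#' @param offset Additive offset in ms (default 0).
#'
#' @return Arrival times in ms.
#' @export
#' @examples
#' bins_to_ms(100, bin_width = 0.132) # 13.2 ms
bins_to_ms <- function(drift_bin, bin_width = 26.4 / 200, offset = 0) {
  check_number(bin_width, "bin_width", positive = TRUE)
  check_number(offset, "offset")
  if (any(!is.finite(drift_bin)) || any(drift_bin < 0)) {
    abort("`drift_bin` must be finite and >= 0.")
  }
  offset + drift_bin * bin_width
}

#' Read a peak-list table
#'
#' Reads one acquisition's detected peaks (m/z, drift, intensity) from a
#' delimited text file, using a [peaklist_dialect()] to locate the columns.
#' Rows whose mapped fields cannot be parsed as numbers, or violate basic
#' validity (m/z <= 0, negative intensity), are reported via a warning and
#' returned flagged in the `malformed` attribute — never silently dropped.
#'
#' @param path Path to a CSV/TSV peak list.
#' @param dialect A [peaklist_dialect()].
#' @param separation_time Separation time of this acquisition in ms.
#' @param polarity `"positive"` or `"negative"`.
#' @param source_id Free-text identifier recorded alongside each peak.
#'
#' @return A tibble with columns `mz`, `arrival_time`, `intensity`,
#'   `separation_time`, `polarity`, `source_id`, in file order.
#'   Attribute `malformed` holds the offending raw rows (possibly 0-row).
#' @export
read_peaklist <- function(path, dialect = peaklist_dialect(),
                          separation_time = NA_real_,
                          polarity = c("positive", "negative"),
                          source_id = basename(path)) {
  polarity <- match.arg(polarity)
  if (!file.exists(path)) abort(sprintf("Peak list not found: %s", path))
  raw <- readr::read_delim(path, delim = guess_delim(path),
                           show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  needed <- c(dialect$mz, dialect$drift, dialect$intensity)
  check_columns(raw, needed, "peak list")
  mz <- suppressWarnings(as.numeric(raw[[dialect$mz]]))
  drift <- suppressWarnings(as.numeric(raw[[dialect$drift]]))
  intensity <- suppressWarnings(as.numeric(raw[[dialect$intensity]]))
  bad <- !is.finite(mz) | !is.finite(drift) | !is.finite(intensity) |
    mz <= 0 | intensity < 0
  if (any(bad)) {
    warn(sprintf("%d malformed row(s) in %s (kept aside, see attr 'malformed').",
                 sum(bad), path))
  }
  if (all(bad)) abort(sprintf("Zero parsable rows in %s", path))
  arrival <- if (dialect$drift_unit == "bin") {
    bins_to_ms(drift[!bad], bin_width = dialect$bin_width, offset = dialect$offset)
  } else {
    drift[!bad]
  }
  out <- tibble(
    mz = mz[!bad],
    arrival_time = arrival,
    intensity = intensity[!bad],
    separation_time = separation_time,
    polarity = polarity,
    source_id = source_id
  )
  attr(out, "malformed") <- raw[bad, , drop = FALSE]
  out
}

guess_delim <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0) return(",")
  if (grepl("\t", first)) "\t" else ","
}

#' Keep the N most intense peaks of each acquisition
#'
#' Standard top-N reduction applied per separation time (vendor software
#' typically exports the 500 most intense peaks).
#'
#' @param peaks A peak tibble (as from [read_peaklist()]), possibly spanning
#'   several separation times.
#' @param n Number of peaks to keep per separation time (default 500).
#'
#' @return The filtered tibble.
#' @export
top_n_peaks <- function(peaks, n = 500) {
  check_number(n, "n", positive = TRUE)
  check_columns(peaks, c("intensity", "separation_time"), "peaks")
  peaks |>
    dplyr::group_by(.data$separation_time) |>
    dplyr::slice_max(.data$intensity, n = n, with_ties = FALSE) |>
    dplyr::ungroup()
}

#' Read a separation-time series from a manifest
#'
#' The manifest is a CSV with columns `file` and `separation_time` (ms), and
#' optionally `polarity` and `source_id`; file paths are resolved relative to
#' the manifest's directory. Separation times must be strictly increasing with
#' no duplicates.
#'
#' @param manifest_path Path to the manifest CSV.
#' @param dialect A [peaklist_dialect()] applied to every listed file.
#'
#' @return One tibble of peaks across the whole series (a separation series),
#'   with a `separation_time` column keying each acquisition.
#' @export
read_series <- function(manifest_path, dialect = peaklist_dialect()) {
  if (!file.exists(manifest_path)) {
    abort(sprintf("Manifest not found: %s", manifest_path))
  }
  man <- readr::read_csv(manifest_path, show_col_types = FALSE, progress = FALSE)
  check_columns(man, c("file", "separation_time"), "manifest")
  st <- man$separation_time
  if (any(diff(st) <= 0)) {
    abort("Manifest separation times must be strictly increasing (no duplicates).")
  }
  base <- dirname(manifest_path)
  purrr::pmap(man, function(file, separation_time, polarity = "positive",
                            source_id = file, ...) {
    read_peaklist(file.path(base, file), dialect = dialect,
                  separation_time = separation_time,
                  polarity = polarity, source_id = source_id)
  }) |>
    purrr::list_rbind()
}

#' Write / read the per-compound series table
#'
#' The series table holds the matched arrival times of every targeted
#' compound at every separation time of the schedule — one row per compound
#' x separation time. The CSV round-trips losslessly with [read_series_table()]
#' (values written at full precision).
#'
#' @param series A tibble with at least `compound`, `adduct`, `mz`,
#'   `separation_time`, `arrival_time` (and optionally `intensity`).
#' @param path Output CSV path.
#'
#' @return `path`, invisibly.
#' @export
write_series_table <- function(series, path) {
  if (!is.data.frame(series) || nrow(series) == 0) {
    abort("`series` must be a non-empty data frame.")
  }
  check_columns(series, c("compound", "adduct", "mz", "separation_time",
                          "arrival_time"), "series")
  out <- as.data.frame(series)
  # serialise doubles with 17 significant digits so the reader restores them
  # bit-identically
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  utils::write.table(out, path, sep = ",", row.names = FALSE, qmethod = "double")
  invisible(path)
}

#' @rdname write_series_table
#' @export
read_series_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("Series table not found: %s", path))
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
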