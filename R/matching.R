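#' Read a compound reference list
#'
#' A reference list names the expected adduct forms of the targeted compounds:
#' columns `compound`, `adduct`, `ref_mz` (Th), and optionally `class_tag`
#' (`"lipid"`/`"nonlipid"`, default lipid) and `role`
#' (`"calibrant"`/`"analyte"`, default analyte). (compound, adduct) pairs must
#' be unique and `ref_mz > 0`.
#'
#' @param path CSV path.
#' @return A tibble with the columns above.
#' @export
read_compound_refs <- function(path) {
  if (!file.exists(path)) abort(sprintf("Reference list not found: %s", path))
  refs <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(refs, c("compound", "adduct", "ref_mz"), "reference list")
  if (!"class_tag" %in% names(refs)) refs$class_tag <- "lipid"
  if (!"role" %in% names(refs)) refs$role <- "analyte"
  validate_compound_refs(refs)
}

validate_compound_refs <- function(refs) {
  if (any(!is.finite(refs$ref_mz)) || any(refs$ref_mz <= 0)) {
    abort("All `ref_mz` must be finite and > 0.")
  }
  key <- paste(refs$compound, refs$adduct, sep = "\r")
  if (anyDuplicated(key)) {
    abort("(compound, adduct) pairs must be unique in the reference list.")
  }
  as_tibble(refs)
}

#' Match peaks to reference compounds by m/z
#'
#' For each reference compound, selects the peak whose m/z lies within
#' `tol_ppm` parts-per-million of the reference m/z (relative to the
#' reference value); when several peaks qualify, the most intense wins.
#' Matching is performed independently within each separation time present in
#' `peaks`. Absence of a match is a valid result, not an error.
#'
#' @param peaks A peak tibble with `mz`, `arrival_time`, `intensity` and
#'   (optionally) `separation_time`.
#' @param refs A reference tibble with `compound`, `adduct`, `ref_mz`
#'   (see [read_compound_refs()]), or a single-row reference.
#' @param tol_ppm Matching tolerance in ppm (default 10); the window is
#'   inclusive (`<=`).
#'
#' @return A tibble with one row per reference compound x separation time that
#'   produced a match: `compound`, `adduct`, `ref_mz`, `mz`, `ppm_error`
#'   (signed), `arrival_time`, `intensity`, `separation_time`.
#' @export
#' @examples
#' peaks <- tibble::tibble(
#'   mz = c(454.2930, 454.2970), arrival_time = c(60, 61),
#'   intensity = c(1000, 5000), separation_time = 50
#' )
#' refs <- tibble::tibble(compound = "LPC(13:0)", adduct = "[M+H]+",
#'                        ref_mz = 454.2928)
#' match_mz(peaks, refs) # the more intense 454.2970 wins
match_mz <- function(peaks, refs, tol_ppm = 10) {
  check_number(tol_ppm, "tol_ppm", positive = TRUE)
  check_columns(peaks, c("mz", "arrival_time", "intensity"), "peaks")
  refs <- validate_compound_refs(as_tibble(refs))
  if (!"separation_time" %in% names(peaks)) peaks$separation_time <- NA_real_
  empty <- tibble(
    compound = character(), adduct = character(), ref_mz = numeric(),
    mz = numeric(), ppm_error = numeric(), arrival_time = numeric(),
    intensity = numeric(), separation_time = numeric()
  )
  out <- purrr::pmap(
    refs[, c("compound", "adduct", "ref_mz")],
    function(compound, adduct, ref_mz) {
      err <- ppm_error(peaks$mz, ref_mz)
      hits <- peaks[abs(err) <= tol_ppm, , drop = FALSE]
      if (nrow(hits) == 0) return(NULL)
      hits |>
        dplyr::group_by(.data$separation_time) |>
        dplyr::slice_max(.data$intensity, n = 1, with_ties = FALSE) |>
        dplyr::ungroup() |>
        dplyr::transmute(
          compound = compound, adduct = adduct, ref_mz = ref_mz,
          mz = .data$mz, ppm_error = ppm_error(.data$mz, ref_mz),
          arrival_time = .data$arrival_time, intensity = .data$intensity,
          separation_time = .data$separation_time
        )
    }
  ) |>
    purrr::list_rbind()
  if (nrow(out) == 0) empty else out
}

#' Screen features against a reference m/z catalogue
#'
#' Retains a feature iff its m/z lies strictly within `tol_da` of at least one
#' catalogue entry (`min |mz - cat_mz| < tol_da`), as used to remove features
#' absent from a lipid structure database before class-level screening.
#' Retention is independent of the ordering of features or catalogue.
#'
#' @param features A tibble with an `mz` column (other columns carried along).
#' @param catalogue Numeric vector of reference m/z values, or a one-column
#'   data frame.
#' @param tol_da Tolerance in Th (default 0.005, strict `<`).
#'
#' @return The retained rows of `features`, with a `catalogue_delta` column
#'   giving the distance to the nearest catalogue entry.
#' @export
screen_mz_catalogue <- function(features, catalogue, tol_da = 0.005) {
  check_number(tol_da, "tol_da", positive = TRUE)
  check_columns(features, "mz", "features")
  if (is.data.frame(catalogue)) catalogue <- catalogue[[1]]
  catalogue <- as.numeric(catalogue)
  if (length(catalogue) == 0 || any(!is.finite(catalogue))) {
    abort("`catalogue` must be a non-empty list of finite m/z values.")
  }
  delta <- vapply(features$mz, function(m) min(abs(m - catalogue)), numeric(1))
  out <- features[delta < tol_da, , drop = FALSE]
  out$catalogue_delta <- delta[delta < tol_da]
  as_tibble(out)
}

#' Read a one-column m/z catalogue
#'
#' @param path Path to a one-column text/CSV file of m/z values (a header
#'   line is tolerated).
#' @return Numeric vector of m/z values.
#' @export
read_mz_catalogue <- function(path) {
  if (!file.exists(path)) abort(sprintf("Catalogue not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  vals <- suppressWarnings(as.numeric(sub(",.*$", "", trimws(lines))))
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) abort(sprintf("No numeric m/z values in %s", path))
  vals
}
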