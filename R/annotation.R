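#' Build multipass arrival-time database entries
#'
#' A database entry stores a species/adduct's m/z, (corrected) t0 and tp, and
#' the multipass arrival times reconstructed for passes 1..`n_max`
#' (`t_n = t0 + n * tp`), so that a single measurement at any separation time
#' can later be mapped to a compound and a pass number.
#'
#' @param fit A `mobility_fit`, or anything [reconstruct_tn()] accepts
#'   (`t0`/`tp` fields).
#' @param species,adduct,mz Identity of the entry; taken from `fit` when it
#'   carries them (`compound`/`adduct`).
#' @param n_max Highest reconstructed pass (default 10).
#' @param corrected Logical: were t0/tp corrected to the reference session?
#' @param provenance Free-text lineage (session id, correction line used).
#'
#' @return A one-row tibble with `species`, `adduct`, `mz`, `t0`, `tp`,
#'   `t1`..`t<n_max>`, `corrected`, `provenance`.
#' @export
#' @examples
#' build_entry(c(6, 11), species = "X", adduct = "[M+H]+", mz = 454.29)
build_entry <- function(fit, species = NULL, adduct = NULL, mz = NA_real_,
                        n_max = 10, corrected = FALSE, provenance = "") {
  if (n_max < 1) abort("`n_max` must be >= 1.")
  if (inherits(fit, "mobility_fit")) {
    species <- species %||% fit$compound
    adduct <- adduct %||% fit$adduct
  }
  if (is.null(species) || is.null(adduct)) {
    abort("`species` and `adduct` are required.")
  }
  tn <- reconstruct_tn(fit, seq_len(n_max))
  t0 <- if (is.numeric(fit) && length(fit) == 2) fit[[1]] else fit$t0
  tp <- if (is.numeric(fit) && length(fit) == 2) fit[[2]] else fit$tp
  entry <- tibble(species = species, adduct = adduct, mz = mz,
                  t0 = t0, tp = tp)
  entry[paste0("t", seq_len(n_max))] <- as.list(tn)
  entry$corrected <- corrected
  entry$provenance <- provenance
  entry
}

#' Assemble a database from a mobility-fit table
#'
#' @param fits Tibble from [extract_mobility()] (or with `compound`, `adduct`,
#'   `mz`, `t0`, `tp` columns).
#' @param n_max Highest reconstructed pass (default 10).
#' @param corrected,provenance Recorded per entry (see [build_entry()]).
#' @param polarity Ionisation polarity recorded in the database metadata.
#'
#' @return A database tibble (one [build_entry()] row per fit) with a `meta`
#'   attribute (`schema_version`, `polarity`, `n_max`).
#' @export
build_database <- function(fits, n_max = 10, corrected = FALSE,
                           provenance = "", polarity = "positive") {
  check_columns(fits, c("compound", "adduct", "mz", "t0", "tp"), "fits")
  entries <- purrr::pmap(
    fits[, c("compound", "adduct", "mz", "t0", "tp")],
    function(compound, adduct, mz, t0, tp) {
      build_entry(list(t0 = t0, tp = tp), species = compound, adduct = adduct,
                  mz = mz, n_max = n_max, corrected = corrected,
                  provenance = provenance)
    }
  ) |>
    purrr::list_rbind()
  attr(entries, "meta") <- list(schema_version = 1L, polarity = polarity,
                                n_max = n_max)
  entries
}

db_n_max <- function(db) {
  tn_cols <- grep("^t[0-9]+$", names(db), value = TRUE)
  tn_cols <- setdiff(tn_cols, "t0")
  if (length(tn_cols) == 0) abort("Database has no reconstructed pass columns.")
  max(as.integer(sub("^t", "", tn_cols)))
}

#' Write / read a multipass arrival-time database
#'
#' Plain-CSV serialisation with a structured comment header (`# key: value`
#' lines: schema version, polarity, reconstructed pass range) so databases
#' can be exchanged between laboratories in transparent units. On load the
#' defining invariant `t_n = t0 + n * tp` is revalidated for every entry and
#' pass (tolerance 1e-9 ms).
#'
#' @param db Database tibble from [build_database()].
#' @param path CSV path.
#' @return `path` invisibly; `read_database()` returns the database tibble
#'   with its `meta` attribute restored.
#' @export
write_database <- function(db, path) {
  meta <- attr(db, "meta") %||% list(schema_version = 1L,
                                     polarity = "positive",
                                     n_max = db_n_max(db))
  header <- c(
    sprintf("# schema_version: %s", meta$schema_version),
    sprintf("# polarity: %s", meta$polarity),
    sprintf("# n_max: %s", meta$n_max)
  )
  writeLines(header, path)
  readr::write_csv(db, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' @rdname write_database
#' @export
read_database <- function(path) {
  if (!file.exists(path)) abort(sprintf("Database not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list(schema_version = 1L, polarity = "positive", n_max = NA_integer_)
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    key <- trimws(sub(":.*$", "", kv))
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- utils::type.convert(val, as.is = TRUE)
  }
  db <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  n_max <- db_n_max(db)
  if (is.na(meta$n_max)) meta$n_max <- n_max
  for (n in seq_len(n_max)) {
    expected <- db$t0 + n * db$tp
    if (any(abs(db[[paste0("t", n)]] - expected) > 1e-9)) {
      abort(sprintf("Database invariant violated: t%d != t0 + %d * tp.", n, n))
    }
  }
  attr(db, "meta") <- meta
  db
}

#' Estimate the pass number of a measured arrival time
#'
#' For a given database entry, returns the pass n (1..n_max) whose
#' reconstructed arrival time lies closest to the measured one; exact ties
#' are broken toward the lower pass.
#'
#' @param measured_tn Measured multipass arrival time (ms).
#' @param entry One database row (or anything with `t0` and `tp`).
#' @param n_max Highest pass considered (default: the entry's reconstructed
#'   range, else 10).
#'
#' @return Integer pass number.
#' @export
#' @examples
#' estimate_pass_number(105.3, list(t0 = 6, tp = 11)) # 9
estimate_pass_number <- function(measured_tn, entry, n_max = NULL) {
  check_number(measured_tn, "measured_tn", positive = TRUE)
  if (is.null(n_max)) {
    n_max <- tryCatch(db_n_max(entry), error = function(e) 10L)
  }
  tn <- reconstruct_tn(list(t0 = entry$t0, tp = entry$tp), seq_len(n_max))
  d <- abs(measured_tn - tn)
  which.min(d) # which.min returns the first (lowest-n) minimum on ties
}

#' Annotate features against the multipass arrival-time database
#'
#' Joint m/z + arrival-time search: for each query feature, database entries
#' within `mz_tol_ppm` of the query m/z are candidates; for each candidate the
#' best-matching pass `n <= max_pass` is determined
#' (`argmin |t - t_n|`, ties to the lower pass) and candidates are ranked by
#' relative arrival-time error `100 * |t - t_n| / t_n` (percent, ascending).
#' Query arrival times should already be corrected to the database session
#' (see [run_annotate()] for the single-measurement workflow).
#'
#' @param queries Tibble with `mz` and `t_n` columns (and optionally
#'   `query_id`; row numbers are used otherwise).
#' @param db Database tibble ([build_database()]/[read_database()]).
#' @param mz_tol_ppm m/z tolerance in ppm (default 20, inclusive).
#' @param max_pass Highest pass searched (default: the database's
#'   reconstructed range). Values beyond that range are refused unless
#'   `extrapolate = TRUE`, in which case arrival times are extended with
#'   `t0 + n * tp`.
#' @param extrapolate Allow `max_pass` beyond the reconstructed range.
#'
#' @return A tibble with one row per (query, candidate): `query_id`,
#'   `query_mz`, `query_tn`, `species`, `adduct`, `mz`, `pass_n`,
#'   `ppm_error`, `tn_error_pct`, `rank` (1 = best per query). Queries with
#'   no m/z match contribute no rows; an empty database yields an empty
#'   result.
#' @export
annotate_features <- function(queries, db, mz_tol_ppm = 20, max_pass = NULL,
                              extrapolate = FALSE) {
  check_number(mz_tol_ppm, "mz_tol_ppm", positive = TRUE)
  queries <- as_tibble(queries)
  check_columns(queries, c("mz", "t_n"), "queries")
  if (!"query_id" %in% names(queries)) {
    queries$query_id <- as.character(seq_len(nrow(queries)))
  }
  empty <- tibble(
    query_id = character(), query_mz = numeric(), query_tn = numeric(),
    species = character(), adduct = character(), mz = numeric(),
    pass_n = integer(), ppm_error = numeric(), tn_error_pct = numeric(),
    rank = integer()
  )
  if (nrow(db) == 0 || nrow(queries) == 0) return(empty)
  db_nmax <- db_n_max(db)
  if (is.null(max_pass)) max_pass <- db_nmax
  if (max_pass > db_nmax && !extrapolate) {
    abort(sprintf(
      "max_pass (%d) exceeds the database's reconstructed range (%d); set `extrapolate = TRUE` to extend with t0 + n * tp.",
      max_pass, db_nmax
    ))
  }
  rows <- purrr::pmap(
    queries[, c("query_id", "mz", "t_n")],
    function(query_id, mz, t_n) {
      perr <- ppm_error(mz, db$mz)
      cand <- db[abs(perr) <= mz_tol_ppm, , drop = FALSE]
      if (nrow(cand) == 0) return(NULL)
      best <- purrr::pmap(
        list(cand$t0, cand$tp),
        function(t0, tp) {
          tn <- t0 + seq_len(max_pass) * tp
          d <- abs(t_n - tn)
          n <- which.min(d)
          tibble(pass_n = n, tn_error_pct = 100 * d[n] / tn[n])
        }
      ) |>
        purrr::list_rbind()
      cand_ppm <- ppm_error(mz, cand$mz)
      out <- tibble(
        query_id = query_id, query_mz = mz, query_tn = t_n,
        species = cand$species, adduct = cand$adduct, mz = cand$mz,
        pass_n = as.integer(best$pass_n),
        ppm_error = cand_ppm,
        tn_error_pct = best$tn_error_pct
      )
      out <- out[order(out$tn_error_pct, out$pass_n), , drop = FALSE]
      out$rank <- seq_len(nrow(out))
      out
    }
  )
  out <- purrr::list_rbind(purrr::compact(rows))
  if (nrow(out) == 0) empty else out
}
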