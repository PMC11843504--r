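# Workflow orchestration: the run_* functions tie the modules into the
# end-to-end workflows (extract -> correct -> build database -> annotate)
# and back the command-line script installed at inst/scripts/cyclim.R.

#' Run configuration
#'
#' Central bundle of tolerances and instrument constants, each traceable to
#' the standard acquisition settings: 10 ppm m/z matching during extraction,
#' 20 ppm during database annotation, 0.005 Da for catalogue screening, 0.7%
#' for residual-based class screening, a 26.4 ms acquisition window resolved
#' into 200 drift bins, and a 0.01 ms zero-pass separation time. A YAML file
#' can override any subset; explicit arguments override the file.
#'
#' @param path Optional YAML file with keys matching the arguments.
#' @param mz_ppm_match,mz_ppm_annotate m/z tolerances (ppm).
#' @param mz_da_screen Catalogue screening tolerance (Th).
#' @param residual_threshold Class screening threshold (%).
#' @param window Acquisition window (ms).
#' @param n_bins Drift bins spanning the window.
#' @param zero_pass_time Zero-pass separation time (ms).
#' @param n_max Reconstructed passes in database entries.
#' @param seed Default RNG seed for simulation commands.
#'
#' @return A list of class `run_config` (with `bin_width = window / n_bins`).
#' @export
run_config <- function(path = NULL, mz_ppm_match = 10, mz_ppm_annotate = 20,
                       mz_da_screen = 0.005, residual_threshold = 0.7,
                       window = 26.4, n_bins = 200, zero_pass_time = 0.01,
                       n_max = 10, seed = 1L) {
  cfg <- list(
    mz_ppm_match = mz_ppm_match, mz_ppm_annotate = mz_ppm_annotate,
    mz_da_screen = mz_da_screen, residual_threshold = residual_threshold,
    window = window, n_bins = n_bins, zero_pass_time = zero_pass_time,
    n_max = n_max, seed = seed
  )
  if (!is.null(path)) {
    if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
    over <- yaml::read_yaml(path)
    supplied <- names(match.call())[-1]
    for (k in setdiff(intersect(names(over), names(cfg)), supplied)) {
      cfg[[k]] <- over[[k]]
    }
  }
  for (k in c("mz_ppm_match", "mz_ppm_annotate", "mz_da_screen",
              "residual_threshold", "window", "zero_pass_time")) {
    check_number(cfg[[k]], k, positive = TRUE)
  }
  cfg$bin_width <- cfg$window / cfg$n_bins
  structure(cfg, class = "run_config")
}

#' Extract mobility parameters from a series on disk
#'
#' Reads a series manifest, applies the top-N intensity filter per
#' acquisition, and runs [extract_mobility()].
#'
#' @param manifest_path Series manifest CSV ([read_series()]).
#' @param refs_path Compound reference list CSV ([read_compound_refs()]).
#' @param config A [run_config()].
#' @param n_top Most intense peaks kept per acquisition (default 500).
#' @param dialect [peaklist_dialect()] for the listed files.
#'
#' @return The [extract_mobility()] tibble.
#' @export
run_extract <- function(manifest_path, refs_path, config = run_config(),
                        n_top = 500, dialect = NULL) {
  if (is.null(dialect)) {
    dialect <- peaklist_dialect(bin_width = config$bin_width)
  }
  peaks <- read_series(manifest_path, dialect = dialect)
  peaks <- top_n_peaks(peaks, n = n_top)
  extract_mobility(peaks, read_compound_refs(refs_path),
                   tol_ppm = config$mz_ppm_match,
                   zero_pass_time = config$zero_pass_time)
}

#' Correct a measured mobility table to a reference, with class screening
#'
#' Wraps [correct_mobility_table()] and, on the corrected tp residuals,
#' [screen_by_residual()]: features whose post-correction residual exceeds
#' the threshold are flagged out-of-class, and when at least two are flagged
#' a group self-correction is attempted ([group_self_correction()]).
#'
#' @param measured,reference Mobility tables (`compound`, `adduct`, `t0`,
#'   `tp`).
#' @param calibrants Calibrant compound names (or tibble with `compound`).
#' @param config A [run_config()] (supplies the screening threshold).
#' @param quantities Quantities to correct (default `c("tp", "t0")`).
#'
#' @return A list: `lines`, `table` (with `class_flag` from the tp
#'   post-correction residual), `mre`, and `self_correction` (NULL when
#'   fewer than 2 features are flagged).
#' @export
run_correct <- function(measured, reference, calibrants,
                        config = run_config(), quantities = c("tp", "t0")) {
  res <- correct_mobility_table(measured, reference, calibrants,
                                quantities = quantities)
  tb <- res$table
  tb$residual_pct <- tb$tp_residual_post_pct
  tb <- screen_by_residual(tb, threshold = config$residual_threshold)
  res$table <- tb
  flagged <- tb[tb$class_flag == "out-of-class" & !tb$is_calibrant, ,
                drop = FALSE]
  res$self_correction <- NULL
  if (nrow(flagged) >= 2) {
    res$self_correction <- group_self_correction(
      tibble(measured = flagged$tp_measured,
             reference = flagged$tp_reference),
      quantity = "tp", original_line = res$lines[["tp"]]
    )
  }
  res
}

#' Single-measurement annotation against a multipass database
#'
#' The one-shot workflow: query features (m/z, measured arrival time) are
#' annotated against the database after aligning their arrival times with a
#' tn correction line built from co-measured calibrant features. Calibrant
#' rows are identified by non-missing `species`/`adduct` columns naming
#' their database entry; their pass numbers are determined by nearest-tn
#' search ([estimate_pass_number()]), the line maps measured tn to database
#' tn, and all query times are corrected before the joint m/z + tn search
#' ([annotate_features()]).
#'
#' @param queries Tibble with `mz`, `t_n`, optional `query_id`, and (for
#'   calibrant rows) `species`/`adduct`.
#' @param db Database tibble.
#' @param config A [run_config()] (annotation ppm tolerance).
#' @param correct Build and apply the tn correction line (default TRUE when
#'   at least 2 calibrant rows are present).
#'
#' @return A list: `line` (the tn `correction_line`, or NULL), `calibrants`
#'   (pass assignments and measured/database tn of the calibrant features),
#'   and `report` (ranked [annotate_features()] output; `query_tn` holds the
#'   corrected time, `query_tn_measured` the original).
#' @export
run_annotate <- function(queries, db, config = run_config(), correct = TRUE) {
  if (nrow(db) == 0) abort("Empty database.")
  queries <- as_tibble(queries)
  check_columns(queries, c("mz", "t_n"), "queries")
  if (!"query_id" %in% names(queries)) {
    queries$query_id <- as.character(seq_len(nrow(queries)))
  }
  is_cal <- if ("species" %in% names(queries)) {
    !is.na(queries$species)
  } else {
    rep(FALSE, nrow(queries))
  }
  line <- NULL
  cal_tbl <- NULL
  measured <- queries$t_n
  if (correct && sum(is_cal) >= 2) {
    cal <- queries[is_cal, , drop = FALSE]
    cal_rows <- purrr::pmap(
      cal[, c("query_id", "species", "adduct", "t_n")],
      function(query_id, species, adduct, t_n) {
        entry <- db[db$species == species & db$adduct == adduct, ,
                    drop = FALSE]
        if (nrow(entry) != 1) {
          abort(sprintf("Calibrant %s %s not found uniquely in the database.",
                        species, adduct))
        }
        n <- estimate_pass_number(t_n, entry)
        tibble(query_id = query_id, species = species, adduct = adduct,
               pass_n = n, measured = t_n,
               reference = entry$t0 + n * entry$tp)
      }
    ) |>
      purrr::list_rbind()
    line <- fit_correction_line(
      cal_rows[, c("measured", "reference")], quantity = "tn"
    )
    cal_tbl <- cal_rows
    queries$t_n <- apply_correction(line, queries$t_n)
  }
  report <- annotate_features(queries, db,
                              mz_tol_ppm = config$mz_ppm_annotate)
  if (nrow(report) > 0) {
    report$query_tn_measured <-
      measured[match(report$query_id, queries$query_id)]
  }
  list(line = line, calibrants = cal_tbl, report = report)
}
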