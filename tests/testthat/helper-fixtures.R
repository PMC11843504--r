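# Fixtures are built in code at test time; nothing binary is stored.

write_peaklist_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# Reference list for a compound tibble from sim_compounds().
refs_from_compounds <- function(cmp, role = "analyte") {
  tibble::tibble(
    compound = cmp$compound, adduct = cmp$adduct, ref_mz = cmp$mz,
    class_tag = cmp$class_tag, role = role
  )
}

# Independent brute-force annotation oracle: scan every (entry, pass) pair.
# Within an entry the pass is the one with the smallest absolute distance to
# the measured arrival time (lowest pass on ties); entries are then ranked by
# relative arrival-time error.
brute_force_annotate <- function(query_mz, query_tn, db, mz_tol_ppm, max_pass) {
  best <- NULL
  for (i in seq_len(nrow(db))) {
    if (abs((query_mz - db$mz[i]) / db$mz[i] * 1e6) > mz_tol_ppm) next
    best_n <- NULL
    for (n in seq_len(max_pass)) {
      tn <- db$t0[i] + n * db$tp[i]
      if (is.null(best_n) || abs(query_tn - tn) < best_n$dist) {
        best_n <- list(n = n, dist = abs(query_tn - tn), tn = tn)
      }
    }
    err <- 100 * best_n$dist / best_n$tn
    if (is.null(best) || err < best$err) {
      best <- list(species = db$species[i], adduct = db$adduct[i],
                   n = best_n$n, err = err)
    }
  }
  best
}

# Per-compound ground-truth pass numbers for the peaks that extraction's
# m/z matching would select (most intense per separation time).
truth_top_per_time <- function(truth) {
  truth |>
    dplyr::group_by(compound, adduct, separation_time) |>
    dplyr::slice_max(intensity, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
}
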