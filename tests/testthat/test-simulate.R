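test_that("the default schedule has the expected shape", {
  sched <- default_schedule()
  expect_equal(sched[1], 0.01)
  expect_equal(length(sched), 48)
  expect_true(all(diff(sched) > 0))
  expect_equal(anyDuplicated(sched), 0)
  expect_equal(max(sched), 150)
})

test_that("noiseless, undrifted emissions sit exactly on the multipass line", {
  cmp <- sim_compounds(4, seed = 101)
  sim <- simulate_series(cmp, seed = 102)
  tr <- sim$truth
  expected <- cmp$t0_true[match(tr$compound, cmp$compound)] +
    tr$n * cmp$tp_true[match(tr$compound, cmp$compound)]
  expect_equal(tr$t_emitted, expected, tolerance = 1e-12)
  # every emission respects the acquisition window
  expect_true(all(tr$t_emitted - tr$separation_time >= -1e-9))
  expect_true(all(tr$t_emitted - tr$separation_time <= 26.4 + 1e-9))
})

test_that("window membership matches hand enumeration and wrap-around mixes passes", {
  cmp <- tibble::tibble(
    compound = c("FAST", "SLOW"), adduct = "[M+H]+", mz = c(500, 600),
    t0_true = c(6, 6), tp_true = c(10, 13),
    base_intensity = 1e4, class_tag = "lipid"
  )
  sim <- simulate_series(cmp, schedule = 30, seed = 103)
  # at T = 30 ms with a 26.4 ms window: 0 <= 6 + 10n - 30 <= 26.4 -> n in 3..5
  #                                     0 <= 6 + 13n - 30 <= 26.4 -> n in 2..3
  fast_n <- sort(sim$truth$n[sim$truth$compound == "FAST"])
  slow_n <- sort(sim$truth$n[sim$truth$compound == "SLOW"])
  expect_equal(fast_n, 3:5)
  expect_equal(slow_n, 2:3)

  # across the full schedule the faster compound overtakes: at some separation
  # times its (later-pass) arrival precedes the slower compound's
  full <- simulate_series(cmp, seed = 104)
  top <- truth_top_per_time(full$truth) |>
    tidyr::pivot_wider(id_cols = separation_time, names_from = compound,
                       values_from = n)
  gap <- top$FAST - top$SLOW
  expect_gt(max(gap, na.rm = TRUE), 0)
})

test_that("emission counts are bounded by the window/cycle ratio", {
  cmp <- sim_compounds(6, seed = 105, tp_range = c(6, 20))
  sim <- simulate_series(cmp, seed = 106)
  counts <- sim$truth |>
    dplyr::group_by(compound, separation_time) |>
    dplyr::summarise(k = dplyr::n(), .groups = "drop")
  bound <- ceiling(26.4 / cmp$tp_true[match(counts$compound, cmp$compound)]) + 1
  expect_true(all(counts$k <= bound))
})

test_that("the same seed reproduces a series; a different seed does not", {
  cmp <- sim_compounds(3, seed = 107)
  drift <- session_drift(noise_cv = 0.001)
  a <- simulate_series(cmp, drift = drift, seed = 108)
  b <- simulate_series(cmp, drift = drift, seed = 108)
  c <- simulate_series(cmp, drift = drift, seed = 109)
  expect_identical(a$peaks, b$peaks)
  expect_false(isTRUE(all.equal(a$peaks$arrival_time, c$peaks$arrival_time)))
})

test_that("two-session simulation exposes the true drift maps", {
  cmp <- sim_compounds(8, seed = 111)
  drift <- session_drift(tp_slope = 0.97, tp_intercept = 0.1, noise_cv = 0)
  two <- simulate_two_sessions(cmp, drift, seed = 112)
  expect_equal(two$true_maps$tp, c(slope = 0.97, intercept = 0.1))
  # identity drift: session values equal the truth in both sessions
  ident <- simulate_two_sessions(cmp, session_drift(), seed = 113)
  expect_equal(ident$session_a$truth$t_emitted,
               ident$session_b$truth$t_emitted, tolerance = 1e-12)
  # drifted session-B cycle times follow the affine map; closed-form MRE
  tp_b <- unique(two$session_b$truth[, c("compound", "tp_session")])
  ord <- match(tp_b$compound, cmp$compound)
  expect_equal(tp_b$tp_session, 0.97 * cmp$tp_true[ord] + 0.1)
  mre_closed <- mean(100 * abs(0.97 * cmp$tp_true + 0.1 - cmp$tp_true) /
                       cmp$tp_true)
  expect_equal(
    mean_relative_error(0.97 * cmp$tp_true + 0.1, cmp$tp_true), mre_closed
  )
  expect_gt(mre_closed, 2) # the drift regime is an interweek-scale shift
})

test_that("class-specific drift labels the ground truth for screening", {
  cmp <- sim_compounds(6, seed = 115,
                       class_tag = rep(c("lipid", "nonlipid"), 3))
  drift <- session_drift(
    tp_slope = 0.97, class_specific = list(class_tag = "nonlipid",
                                           tp_slope = 0.90)
  )
  vals <- simulate_session_values(cmp, drift, seed = 116)
  expect_equal(vals$tp_b[vals$class_tag == "lipid"],
               0.97 * vals$tp_true[vals$class_tag == "lipid"])
  expect_equal(vals$tp_b[vals$class_tag == "nonlipid"],
               0.90 * vals$tp_true[vals$class_tag == "nonlipid"])
})

test_that("extraction recovers tp within 0.1% in >=95% of noisy replicates", {
  hits <- 0; total <- 0
  for (r in 1:200) {
    cmp <- sim_compounds(2, seed = 1000 + r)
    sim <- simulate_series(cmp, drift = session_drift(noise_cv = 0.001),
                           seed = 2000 + r)
    # noise occasionally pushes an arrival just below its separation time;
    # that is the flag the extraction is expected to raise, not a failure
    fits <- suppressWarnings(
      extract_mobility(sim$peaks, refs_from_compounds(cmp))
    )
    ord <- match(fits$compound, cmp$compound)
    rel <- abs(fits$tp - cmp$tp_true[ord]) / cmp$tp_true[ord]
    hits <- hits + sum(rel < 0.001)
    total <- total + length(rel)
  }
  expect_gte(hits / total, 0.95)
})
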