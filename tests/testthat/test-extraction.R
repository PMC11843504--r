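test_that("measure_t0 reads the zero-pass arrival time via m/z matching", {
  refs <- tibble::tibble(compound = "LPC(13:0)", adduct = "[M+H]+",
                         ref_mz = 454.2928)
  zero <- tibble::tibble(mz = 454.2929, arrival_time = 6.40, intensity = 100,
                         separation_time = 0.01)
  t0 <- measure_t0(zero, refs)
  expect_equal(t0$t0, 6.40)

  # two peaks in window: the match_mz intensity rule decides
  two <- tibble::tibble(mz = c(454.2929, 454.2960),
                        arrival_time = c(6.40, 6.55),
                        intensity = c(100, 900), separation_time = 0.01)
  oracle <- match_mz(two, refs, tol_ppm = 10)
  expect_equal(measure_t0(two, refs)$t0, oracle$arrival_time)
  expect_equal(measure_t0(two, refs)$t0, 6.55)

  none <- tibble::tibble(mz = 500, arrival_time = 6, intensity = 1,
                         separation_time = 0.01)
  expect_error(measure_t0(none, refs), "t0 unavailable")
  wrong <- zero; wrong$separation_time <- 1
  expect_error(measure_t0(wrong, refs), "separation time")
})

test_that("pass numbers on an exact multipass line are recovered directly", {
  arr <- tibble::tibble(separation_time = c(10, 20, 30, 40, 50),
                        arrival_time = c(17, 28, 39, 50, 61))
  out <- assign_pass_numbers(arr, t0 = 6)
  expect_equal(out$n, 1:5)
  expect_equal(out$residual, rep(0, 5), tolerance = 1e-12)

  single <- arr[1, ]
  expect_error(assign_pass_numbers(single, t0 = 6), "Cannot assign")
  expect_equal(assign_pass_numbers(single, t0 = 6, tp_seed = 11)$n, 1L)
})

test_that("wrap-around assignments match simulator ground truth", {
  cmp <- tibble::tibble(
    compound = c("FAST", "SLOW"), adduct = "[M+H]+",
    mz = c(500.00, 600.00), t0_true = c(6, 6), tp_true = c(10, 13),
    base_intensity = c(5e4, 5e4), class_tag = "lipid"
  )
  sim <- simulate_series(cmp, seed = 31)
  refs <- refs_from_compounds(cmp)
  matched <- match_mz(sim$peaks, refs)
  top_truth <- truth_top_per_time(sim$truth)
  for (cname in cmp$compound) {
    arr <- matched[matched$compound == cname &
                     matched$separation_time > 0.011, ]
    t0 <- cmp$t0_true[cmp$compound == cname]
    out <- assign_pass_numbers(arr, t0 = t0)
    tru <- top_truth[top_truth$compound == cname &
                       top_truth$separation_time > 0.011, ]
    expect_equal(
      out$n, tru$n[match(out$separation_time, tru$separation_time)]
    )
  }
})

test_that("fit_mobility recovers slope/intercept and flags short fits", {
  obs <- tibble::tibble(n = 1:5, t_n = c(17, 28, 39, 50, 61))
  fit <- fit_mobility(obs)
  expect_equal(fit$tp, 11)
  expect_equal(fit$t0_fit, 6)
  expect_equal(fit$r2, 1)
  expect_equal(fit$quality_flag, "ok")
  expect_equal(fit$n_passes_used, 5)

  short <- fit_mobility(obs[1:4, ])
  expect_equal(short$quality_flag, "low_pass_count")
  expect_error(fit_mobility(obs[1, ]), "2 distinct")

  # replicated passes enter as per-pass means
  dup <- tibble::tibble(n = c(1, 1, 2, 3, 4, 5),
                        t_n = c(16.9, 17.1, 28, 39, 50, 61))
  expect_equal(fit_mobility(dup)$tp, 11)
})

test_that("slope recovery under multiplicative noise is unbiased (CV 0.1%)", {
  set.seed(41)
  true_tp <- 11; true_t0 <- 6
  est <- replicate(200, {
    n <- 1:8
    t <- (true_t0 + n * true_tp) * (1 + rnorm(8, 0, 0.001))
    fit_mobility(tibble::tibble(n = n, t_n = t))$tp
  })
  se <- stats::sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - true_tp), 3 * se)
  expect_gt(mean(abs(est - true_tp) / true_tp < 0.005), 0.95)
})

test_that("reconstruct_tn is the multipass line and telescopes by tp", {
  expect_equal(reconstruct_tn(c(6, 11), 9), 105)
  expect_equal(reconstruct_tn(list(t0 = 6, tp = 11), 0), 6)
  expect_error(reconstruct_tn(c(6, 11), -1), ">= 0")
  fit <- fit_mobility(tibble::tibble(n = 1:6, t_n = 6 + 11.3 * (1:6)))
  tns <- reconstruct_tn(fit, 0:12)
  expect_equal(diff(tns), rep(fit$tp, 12))
})

test_that("reconstruction error stays below 0.3% at intraday noise levels", {
  cmp <- sim_compounds(6, seed = 43)
  sim <- simulate_series(cmp, drift = session_drift(noise_cv = 0.001),
                         seed = 44)
  fits <- extract_mobility(sim$peaks, refs_from_compounds(cmp))
  for (i in seq_len(nrow(fits))) {
    truth_row <- cmp[cmp$compound == fits$compound[i], ]
    true_tn <- truth_row$t0_true + (1:8) * truth_row$tp_true
    rec <- reconstruct_tn(fits$fit[[i]], 1:8)
    expect_lt(max(100 * abs(rec - true_tn) / true_tn), 0.3)
  }
})

test_that("three-point tp recovers pass number and cycle time", {
  exact <- three_point_tp(2, 12, 52)
  expect_equal(exact$n, 5L)
  expect_equal(exact$tp, 10)
  expect_equal(exact$consistency, 0)

  off <- three_point_tp(2, 12, 51.8)
  expect_equal(off$n, 5L)
  expect_equal(off$tp, 9.96)
  expect_equal(off$n_raw, 4.98)

  expect_error(three_point_tp(12, 12, 50), "exceed")
  expect_error(three_point_tp(2, 12, 11), ">=")
})

test_that("three-point tp agrees with the slope fit on noiseless lines", {
  set.seed(47)
  for (i in 1:20) {
    t0 <- runif(1, 5, 8); tp <- runif(1, 10, 14); k <- sample(2:10, 1)
    ns <- c(1, k)
    fit <- fit_mobility(tibble::tibble(n = ns, t_n = t0 + ns * tp))
    three <- three_point_tp(t0, t0 + tp, t0 + k * tp)
    expect_equal(three$tp, fit$tp, tolerance = 1e-9)
    expect_equal(three$n, k)
  }
})

test_that("noiseless extraction recovers truth to machine precision", {
  cmp <- sim_compounds(5, seed = 51)
  sim <- simulate_series(cmp, seed = 52)
  fits <- extract_mobility(sim$peaks, refs_from_compounds(cmp))
  expect_equal(nrow(fits), 5)
  ord <- match(fits$compound, cmp$compound)
  expect_equal(fits$tp, cmp$tp_true[ord], tolerance = 1e-12)
  expect_equal(fits$t0, cmp$t0_true[ord], tolerance = 1e-12)
  expect_true(all(fits$flag == "ok"))
})
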