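test_that("an exact affine relation is recovered exactly", {
  m <- c(10, 11, 12, 13, 14)
  line <- fit_correction_line(
    tibble::tibble(measured = m, reference = 1.02 * m - 0.5), "tp"
  )
  expect_equal(line$slope, 1.02)
  expect_equal(line$intercept, -0.5)
  expect_equal(line$r2, 1)
  expect_error(fit_correction_line(
    tibble::tibble(measured = 10, reference = 10), "tp"), "At least 2")
  expect_error(fit_correction_line(
    tibble::tibble(measured = c(10, 10), reference = c(10, 11)), "tp"),
    "Degenerate")
})

test_that("5 calibrants at noise CV 0.05% give slope within 3 SE, r2 > 0.9999", {
  set.seed(61)
  m <- c(10, 11, 12, 13, 14)
  slopes <- replicate(100, {
    ref <- (1.03 * m - 0.2) * (1 + rnorm(5, 0, 5e-4))
    fit_correction_line(tibble::tibble(measured = m, reference = ref),
                        "tp")$slope
  })
  se <- stats::sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 1.03), 3 * se)
  set.seed(62)
  ref <- (1.03 * m - 0.2) * (1 + rnorm(5, 0, 5e-4))
  line <- fit_correction_line(tibble::tibble(measured = m, reference = ref),
                              "tp")
  expect_gt(line$r2, 0.9999)
})

test_that("apply_correction is affine, invertible and order-preserving", {
  m <- c(10, 11, 12, 13, 14)
  identity_line <- fit_correction_line(
    tibble::tibble(measured = m, reference = m), "tp"
  )
  vals <- c(9.5, 12.2, 13.7)
  expect_equal(apply_correction(identity_line, vals), vals)

  line <- fit_correction_line(
    tibble::tibble(measured = m, reference = 0.97 * m + 0.1), "tp"
  )
  originals <- c(10.3, 11.7, 13.9)
  distorted <- (originals - 0.1) / 0.97
  expect_equal(apply_correction(line, distorted), originals,
               tolerance = 1e-12)
  set.seed(63)
  x <- runif(50, 8, 20)
  expect_equal(order(apply_correction(line, x)), order(x))
})

test_that("calibrant self-residuals equal the fit residuals", {
  set.seed(64)
  m <- runif(6, 10, 14)
  ref <- (0.98 * m + 0.3) * (1 + rnorm(6, 0, 1e-3))
  line <- fit_correction_line(tibble::tibble(measured = m, reference = ref),
                              "tp")
  corrected <- apply_correction(line, m)
  expect_equal(100 * abs(corrected - ref) / ref, line$calibrants$residual_pct)
})

test_that("mean relative error matches the worked decimals", {
  expect_equal(round(mean_relative_error(117.01, 114.32), 2), 2.35)
  expect_equal(round(mean_relative_error(111.65, 109.22), 2), 2.22)
  expect_equal(mean_relative_error(c(5, 10), c(5, 10)), 0)
  # invariant under common rescaling
  set.seed(65)
  v <- runif(10, 100, 120); r <- runif(10, 100, 120)
  expect_equal(mean_relative_error(3.7 * v, 3.7 * r),
               mean_relative_error(v, r))
  expect_error(mean_relative_error(1:3, 1:2), "equal")
  expect_error(mean_relative_error(1, 0), "> 0")
})

test_that("post-correction error of analytes vanishes as noise vanishes", {
  run_at <- function(cv, seed) {
    cmp <- sim_compounds(20, seed = 100)
    drift <- session_drift(tp_slope = 0.97, tp_intercept = 0.1,
                           t0_slope = 0.99, t0_intercept = 0.05,
                           noise_cv = cv)
    vals <- simulate_session_values(cmp, drift, seed = seed)
    cal <- vals[1:5, ]; ana <- vals[6:20, ]
    line <- fit_correction_line(
      tibble::tibble(measured = cal$tp_b, reference = cal$tp_a), "tp"
    )
    mean_relative_error(apply_correction(line, ana$tp_b), ana$tp_a)
  }
  expect_lt(run_at(0, 71), 1e-10)
  expect_lt(run_at(1e-4, 72), 0.05)
  expect_lt(run_at(5e-4, 73), 0.2) # the headline post-correction regime
})

test_that("residual screening flags strictly above the threshold", {
  res <- screen_by_residual(
    tibble::tibble(feature = c("a", "b", "c"),
                   residual_pct = c(0.1, 0.2, 1.5)),
    threshold = 0.7
  )
  expect_equal(res$class_flag, c("in-class", "in-class", "out-of-class"))
  all_in <- screen_by_residual(tibble::tibble(residual_pct = c(0.1, 0.7)))
  expect_true(all(all_in$class_flag == "in-class")) # 0.7 itself is in-class
})

test_that("two-class drift is recovered by screening + self-correction", {
  cmp <- sim_compounds(16, seed = 81,
                       class_tag = rep(c("lipid", "nonlipid"), c(10, 6)))
  drift <- session_drift(
    tp_slope = 0.97, tp_intercept = 0.1, noise_cv = 2e-4,
    class_specific = list(class_tag = "nonlipid",
                          tp_slope = 0.90, tp_intercept = 0)
  )
  vals <- simulate_session_values(cmp, drift, seed = 82)
  lip <- vals[vals$class_tag == "lipid", ]
  line <- fit_correction_line(
    tibble::tibble(measured = lip$tp_b[1:5], reference = lip$tp_a[1:5]), "tp"
  )
  vals$residual_pct <- 100 *
    abs(apply_correction(line, vals$tp_b) - vals$tp_a) / vals$tp_a
  screened <- screen_by_residual(vals, threshold = 0.7)
  expect_setequal(
    screened$compound[screened$class_flag == "out-of-class"],
    vals$compound[vals$class_tag == "nonlipid"]
  )
  flagged <- screened[screened$class_flag == "out-of-class", ]
  grp <- group_self_correction(
    tibble::tibble(measured = flagged$tp_b, reference = flagged$tp_a),
    quantity = "tp", original_line = line
  )
  expect_lt(grp$mre_group_pct, grp$mre_original_pct)
  expect_error(group_self_correction(
    tibble::tibble(measured = 1, reference = 1)), "at least 2")
})

test_that("group self-correction is exact on an exact group map", {
  m <- c(11, 12, 13)
  grp <- group_self_correction(
    tibble::tibble(measured = m, reference = 0.95 * m + 0.2)
  )
  expect_equal(grp$mre_group_pct, 0, tolerance = 1e-10)
  expect_true(is.na(grp$mre_original_pct))
})

test_that("cross-class calibrant use warns but proceeds", {
  pairs <- tibble::tibble(measured = c(10, 12, 14), reference = c(10, 12, 14),
                          class_tag = "nonlipid")
  expect_warning(line <- fit_correction_line(pairs, "tp",
                                             analyte_class = "lipid"),
                 "recommended")
  expect_equal(line$slope, 1)
})
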