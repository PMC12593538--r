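noiseless_meas <- function(essx, essy, ...) {
  g <- simulate_fof_grid(ess_pair(essx, essy), ...)
  g$kind <- "measured"
  g
}

test_that("sweeps record both extreme-field differences and survive failures", {
  eng <- synthetic_fof_engine()
  meas <- noiseless_meas(0.7, 0.7)
  sw <- sweep_extreme_fields(eng, meas, ess_grid_spec(), "x",
                             fixed_mm = 0.7)
  expect_equal(nrow(sw), 9L)
  expect_true(all(sw$ok))
  # the difference crosses zero exactly at the true essx
  at_truth <- sw$diff_y4_x05[sw$essx_mm == 0.7]
  expect_equal(at_truth, 0, tolerance = 1e-9)
  expect_true(all(sw$diff_y4_x05[sw$essx_mm < 0.7] > 0))
  expect_true(all(sw$diff_y4_x05[sw$essx_mm > 0.7] < 0))
  # a measured grid equal to the engine output zeroes every row
  sw0 <- sweep_extreme_fields(eng, noiseless_meas(0.5, 0.5),
                              ess_grid_spec(values_mm = c(0.5)), "x",
                              fixed_mm = 0.5)
  expect_equal(sw0$diff_y4_x05, 0, tolerance = 1e-9)
  # table engines fail cleanly on never-evaluated combinations
  sweeps <- reference_ess_sweeps()
  teng <- table_diff_engine(sweeps[["4x0.5"]], sweeps[["0.5x4"]])
  swt <- sweep_extreme_fields(teng, candidates = ess_grid_spec(),
                              free_axis = "x", fixed_mm = 0.7)
  expect_false(all(swt$ok))                 # the (0.7, 0.4) hole
  expect_equal(sum(!swt$ok), 1L)
  expect_equal(swt$diff_y05_x4[swt$essx_mm == 0],  2.65)
  expect_equal(swt$diff_y05_x4[swt$essx_mm == 1.5], -11.29)
})

test_that("sequential optimization recovers noiseless synthetic truths exactly", {
  eng <- synthetic_fof_engine()
  cand <- ess_grid_spec()
  withr::with_seed(31, {
    truths <- cbind(sample(cand$values_mm, 12, replace = TRUE),
                    sample(cand$values_mm, 12, replace = TRUE))
  })
  for (i in seq_len(nrow(truths))) {
    res <- optimize_sequential(eng, noiseless_meas(truths[i, 1], truths[i, 2]),
                               cand)
    expect_equal(res$essx_point, truths[i, 1])
    expect_equal(res$essy_point, truths[i, 2])
    expect_lte(diff(res$essx_mm), 0.5)      # interval spans few candidates
  }
  # perfect model at the start point gives degenerate zero residuals
  res0 <- optimize_sequential(eng, noiseless_meas(0, 0),
                              ess_grid_spec(values_mm = c(0, 0.5, 1),
                                            tie_tolerance_pct = 1e-6))
  expect_equal(res0$essx_mm, c(0, 0))
  expect_equal(res0$essy_mm, c(0, 0))
  expect_equal(res0$residual_x_pct, 0, tolerance = 1e-9)
})

test_that("replaying the packaged sweep tables lands on the published optimum", {
  sweeps <- reference_ess_sweeps()
  eng <- table_diff_engine(sweeps[["4x0.5"]], sweeps[["0.5x4"]])
  res <- optimize_sequential(eng)
  expect_true(res$essx_point %in% c(0.7, 0.8))
  expect_true(res$essy_point %in% c(0.7, 0.8))
  expect_true(res$essx_mm[1] <= 0.7 && res$essx_mm[2] >= 0.8)
  expect_true(res$essy_mm[1] <= 0.7 && res$essy_mm[2] >= 0.8)
  expect_true(all(c(0.7, 0.8) %in% res$essx_tied))
  expect_true(all(c(0.7, 0.8) %in% res$essy_tied))
})

test_that("joint and sequential optima agree on noiseless synthetic data", {
  eng <- synthetic_fof_engine()
  for (truth in list(c(0.5, 0.9), c(0.8, 0.4))) {
    meas <- noiseless_meas(truth[1], truth[2])
    seq_res <- optimize_sequential(eng, meas)
    joint <- optimize_joint(eng, meas, objective = "max_abs")
    expect_equal(joint$essx_point, seq_res$essx_point)
    expect_equal(joint$essy_point, seq_res$essy_point)
    worst <- function(r) max(abs(r$residual_x_pct), abs(r$residual_y_pct))
    expect_lte(worst(joint),
               worst(seq_res) + ess_grid_spec()$tie_tolerance_pct)
  }
})

test_that("an all-tied joint objective reports full-range intervals with a warning", {
  sweeps <- reference_ess_sweeps()
  zero <- sweeps[["4x0.5"]]
  zero[!is.na(zero)] <- 0
  eng <- table_diff_engine(zero, zero)
  cand <- ess_grid_spec(values_mm = c(0, 0.7, 1.5))
  expect_warning(res <- optimize_joint(eng, candidates = cand,
                                       objective = "max_abs"),
                 "degenerate")
  expect_equal(res$essx_mm, c(0, 1.5))
  expect_equal(res$essy_mm, c(0, 1.5))
})

test_that("sign diagnosis labels candidates and flags non-monotone runs", {
  eng <- synthetic_fof_engine()
  sw <- sweep_extreme_fields(eng, noiseless_meas(0.7, 0.7),
                             ess_grid_spec(), "x", fixed_mm = 0.7)
  diag <- sign_diagnosis(sw)
  expect_true(diag$monotone)
  expect_true(all(diag$labels$side[diag$labels$ess_mm < 0.7] ==
                  "below_optimum"))
  expect_true(all(diag$labels$side[diag$labels$ess_mm > 0.7] ==
                  "above_optimum"))
  # the published essx run of the (Y=0.5, X=4) field falls monotonically
  sweeps <- reference_ess_sweeps()
  teng <- table_diff_engine(sweeps[["4x0.5"]], sweeps[["0.5x4"]])
  swt <- sweep_extreme_fields(teng, candidates = ess_grid_spec(),
                              free_axis = "x", fixed_mm = 0.7)
  diag2 <- sign_diagnosis(swt, field = "y05_x4")
  expect_true(diag2$monotone)
  expect_equal(diag2$labels$diff_pct[1], 2.65)
  expect_equal(diag2$labels$diff_pct[nrow(diag2$labels)], -11.29)
  # a contrived rise is listed, not fatal
  swt$diff_y05_x4[swt$essx_mm == 0.8] <- 5
  diag3 <- sign_diagnosis(swt, field = "y05_x4")
  expect_false(diag3$monotone)
  expect_gte(nrow(diag3$violations), 1L)
})

test_that("traces are exhaustive and replayable", {
  eng <- synthetic_fof_engine()
  meas <- noiseless_meas(0.6, 0.8)
  r1 <- optimize_sequential(eng, meas)
  r2 <- optimize_sequential(eng, meas)
  expect_identical(r1$trace, r2$trace)
  expect_equal(nrow(r1$trace), 18L)
  # the optimum appears in the trace
  expect_true(any(r1$trace$essx_mm == r1$essx_point &
                  r1$trace$essy_mm == r1$essy_point))
})
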