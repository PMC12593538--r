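msr_reading <- function(value = 1.0)
  reading_set(field_spec(4, 4), value)

test_that("compute_fof is the corrected reading ratio", {
  clin <- reading_set(field_spec(0.5, 4), 0.620)
  m <- compute_fof(clin, msr_reading(1.000), ocf = 1.026)
  expect_equal(m$fof, 0.63612, tolerance = 1e-12)
  # identity factor and self-normalization
  expect_equal(compute_fof(clin, msr_reading(), 1.0)$fof, 0.620)
  expect_equal(compute_fof(msr_reading(0.5), msr_reading(0.5), 1.0)$fof, 1.0)
  # scale invariance of the reading ratio
  withr::with_seed(3, {
    for (s in runif(20, 0.1, 50)) {
      a <- reading_set(field_spec(1, 2), 0.81 * s)
      b <- msr_reading(1.07 * s)
      expect_equal(compute_fof(a, b, 1.02)$fof, 0.81 / 1.07 * 1.02,
                   tolerance = 1e-12)
    }
  })
  expect_error(compute_fof(clin, msr_reading(), 1.06), "validity band")
  expect_error(reading_set(field_spec(1, 1), -2), "positive")
})

test_that("build_fof_grid places 49 measurements and flags gaps and conflicts", {
  sides <- default_field_sides()
  ms <- list()
  for (y in sides) for (x in sides)
    ms[[length(ms) + 1L]] <- compute_fof(
      reading_set(field_spec(y, x), 0.6 + 0.004 * (y + x)), msr_reading(),
      1.0)
  full <- build_fof_grid(ms)
  expect_equal(dim(full$grid$values), c(7L, 7L))
  expect_equal(sum(!is.na(full$grid$values)), 49L)
  expect_equal(nrow(full$gaps), 0L)
  partial <- build_fof_grid(ms[-17])
  expect_equal(nrow(partial$gaps), 1L)
  expect_error(build_fof_grid(c(ms, ms[3])), "duplicate")
  off_axis <- compute_fof(reading_set(field_spec(0.7, 1), 0.7),
                          msr_reading(), 1.0)
  expect_error(build_fof_grid(list(off_axis)), "not on the grid")
})

test_that("difference grids follow the stated convention and vanish on identity", {
  meas <- reference_fof_grid("6X")
  calc <- meas
  calc$kind <- "calculated"
  d0 <- difference_grid(calc, meas)
  expect_true(all(d0$values == 0))
  calc$values[1, 1] <- 0.637
  meas$values[1, 1] <- 0.636
  expect_equal(difference_grid(calc, meas, "relative")$values[1, 1],
               100 * 0.001 / 0.636, tolerance = 1e-9)
  expect_equal(difference_grid(calc, meas, "absolute")$values[1, 1], 0.1,
               tolerance = 1e-9)
  other <- fof_grid(matrix(1, 2, 2), c(1, 2), c(1, 2), "measured")
  expect_error(difference_grid(calc, other), "axes differ")
})

test_that("summarize_diff computes mean, sample SD, and range", {
  const <- fof_grid(matrix(0.4, 7, 7), kind = "difference_percent")
  s <- summarize_diff(const)
  expect_equal(s$mean_pct, 0.4)
  expect_equal(s$sd_pct, 0)
  expect_equal(c(s$min_pct, s$max_pct), c(0.4, 0.4))
  expect_equal(s$n_cells, 49L)
  s2 <- summarize_diff(const, exclude_msr = TRUE)
  expect_equal(s2$n_cells, 48L)
  # cross-check against stats on the raw cells for a real grid
  d <- reference_diff_grid("6X")
  s3 <- summarize_diff(d)
  expect_equal(s3$mean_pct, mean(d$values))
  expect_equal(s3$sd_pct, sd(as.numeric(d$values)))
})

test_that("extreme_field_differences returns the two elongated-field cells", {
  d <- reference_diff_grid("6X")
  ex <- extreme_field_differences(d)
  expect_equal(unname(ex["y4_x05"]), 0.0)   # (Y=4, X=0.5) cell
  expect_equal(unname(ex["y05_x4"]), 0.0)   # (Y=0.5, X=4) cell
  zero <- fof_grid(matrix(0, 7, 7), kind = "difference_percent")
  expect_equal(unname(extreme_field_differences(zero)), c(0, 0))
  d$values[7, 1] <- NA
  expect_error(extreme_field_differences(d), "missing")
  small <- fof_grid(matrix(0, 2, 2), c(1, 2), c(1, 2),
                    kind = "difference_percent")
  expect_error(extreme_field_differences(small), "not on the grid")
})

test_that("grid CSV round-trip is bit-exact and preserves metadata", {
  g <- reference_fof_grid("6FFF")
  path <- withr::local_tempfile(fileext = ".csv")
  write_fof_grid(g, path)
  g2 <- read_fof_grid(path)
  expect_identical(g2$values, g$values)
  expect_equal(g2$kind, "measured")
  expect_equal(g2$beam_quality, "6FFF")
  expect_equal(g2$y_sides_cm, g$y_sides_cm)
  d <- reference_diff_grid("6X")
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_fof_grid(d, path2)
  d2 <- read_fof_grid(path2)
  expect_identical(d2$values, d$values)
  expect_equal(d2$convention, "as_published")
})
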