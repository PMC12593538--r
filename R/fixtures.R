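# Reference datasets transcribed from a published HD-MLC TrueBeam
# commissioning study (microDiamond measurements, TRS-483 workflow):
# measured FOF grids, calculated-minus-measured difference grids at the
# optimized ESS, and the 6X ESS-sweep difference tables for the three most
# informative fields.  Stored X-major as printed (rows = X, columns = Y) and
# transposed into the package's Y-major convention.

ref_sides <- c(0.5, 1, 1.5, 2, 2.5, 3, 4)

ref_fof_x_major <- list(
  "6X" = matrix(c(
    0.636, 0.686, 0.700, 0.705, 0.708, 0.710, 0.711,
    0.737, 0.819, 0.845, 0.857, 0.865, 0.868, 0.872,
    0.763, 0.858, 0.892, 0.908, 0.918, 0.924, 0.930,
    0.773, 0.872, 0.912, 0.931, 0.943, 0.951, 0.958,
    0.777, 0.880, 0.920, 0.945, 0.957, 0.965, 0.975,
    0.779, 0.883, 0.927, 0.950, 0.965, 0.973, 0.984,
    0.782, 0.888, 0.933, 0.959, 0.975, 0.985, 1.000), 7, 7, byrow = TRUE),
  "6FFF" = matrix(c(
    0.662, 0.705, 0.718, 0.723, 0.726, 0.727, 0.729,
    0.757, 0.828, 0.852, 0.863, 0.869, 0.873, 0.877,
    0.779, 0.863, 0.894, 0.907, 0.916, 0.922, 0.929,
    0.787, 0.875, 0.910, 0.929, 0.938, 0.946, 0.955,
    0.792, 0.882, 0.920, 0.940, 0.953, 0.960, 0.972,
    0.794, 0.887, 0.926, 0.948, 0.962, 0.971, 0.983,
    0.797, 0.893, 0.934, 0.958, 0.973, 0.984, 1.000), 7, 7, byrow = TRUE))

ref_diff_x_major <- list(
  "6X" = matrix(c(
    0.2, 0.4, 0.2, 0.1, 0.1, 0.0,  0.0,
    0.5, 0.7, 0.7, 0.5, 0.2, 0.1,  0.1,
    0.2, 0.6, 0.5, 0.4, 0.1, 0.0, -0.1,
    0.1, 0.6, 0.5, 0.4, 0.2, 0.0,  0.1,
    0.1, 0.6, 0.6, 0.2, 0.2, 0.1,  0.0,
    0.0, 0.6, 0.5, 0.4, 0.2, 0.2,  0.2,
    0.0, 0.6, 0.6, 0.4, 0.2, 0.1,  0.0), 7, 7, byrow = TRUE),
  "6FFF" = matrix(c(
    1.0, 1.1, 0.9, 0.7, 0.6, 0.6, 0.5,
    0.9, 1.0, 0.9, 0.6, 0.5, 0.3, 0.3,
    0.7, 0.8, 0.7, 0.6, 0.4, 0.2, 0.2,
    0.6, 0.8, 0.8, 0.6, 0.5, 0.3, 0.2,
    0.4, 0.8, 0.7, 0.5, 0.3, 0.3, 0.1,
    0.3, 0.7, 0.7, 0.5, 0.3, 0.2, 0.1,
    0.2, 0.6, 0.6, 0.4, 0.3, 0.1, 0.0), 7, 7, byrow = TRUE))

ref_ess_values <- c(0, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1, 1.5)

# Sparse ESS-sweep matrices, 6X: rows = ESSy, columns = ESSx (as printed;
# only the evaluated combinations carry values).
make_sweep <- function(rows) {
  m <- matrix(NA_real_, 9, 9,
              dimnames = list(as.character(ref_ess_values),
                              as.character(ref_ess_values)))
  for (r in names(rows)) {
    vals <- rows[[r]]
    m[r, names(vals)] <- vals
  }
  m
}

ref_sweeps_6x <- list(
  "4x0.5" = make_sweep(list(
    "0"   = c("0" = 1.10, "0.7" = 1.11, "1.5" = 1.17),
    "0.4" = c("0.5" = 0.75, "0.7" = 0.76, "0.8" = 0.76, "0.9" = 0.77),
    "0.5" = c("0.4" = 0.75, "0.5" = 0.75, "0.6" = 0.75, "0.7" = 0.76,
              "0.8" = 0.76, "0.9" = 0.77, "1" = 0.72),
    "0.6" = c("0.5" = 0.60, "0.6" = 0.60, "0.7" = 0.61, "0.8" = 0.61,
              "0.9" = 0.61, "1" = 0.56),
    "0.7" = c("0" = 0.03, "0.5" = 0.03, "0.6" = 0.03, "0.7" = 0.01,
              "0.8" = 0.01, "0.9" = 0.01, "1" = 0.02, "1.5" = 0.07),
    "0.8" = c("0.5" = 0.03, "0.6" = 0.03, "0.7" = 0.01, "0.8" = 0.01,
              "0.9" = 0.01, "1" = 0.02),
    "0.9" = c("0.4" = -0.83, "0.5" = -0.83, "0.6" = -0.83, "0.7" = -0.84,
              "0.8" = -0.84, "0.9" = -0.84, "1" = -0.84),
    "1"   = c("0.5" = -0.85, "0.6" = -0.85, "0.7" = -0.85, "0.8" = -0.85,
              "0.9" = -0.85, "1" = -0.87, "1.5" = -0.80),
    "1.5" = c("0" = -6.11, "0.7" = -6.09, "1.5" = -1.55))),
  "0.5x4" = make_sweep(list(
    "0"   = c("0" = 2.60, "0.7" = -0.03, "1.5" = -11.29),
    "0.4" = c("0.5" = 1.42, "0.7" = -0.03, "0.8" = -0.03, "0.9" = -1.90),
    "0.5" = c("0.4" = 1.42, "0.5" = 1.42, "0.6" = 1.18, "0.7" = -0.03,
              "0.8" = -0.03, "0.9" = -1.90, "1" = -1.96),
    "0.6" = c("0.5" = 1.42, "0.6" = 1.18, "0.7" = -0.03, "0.8" = -0.03,
              "0.9" = -1.90, "1" = -1.96),
    "0.7" = c("0" = 2.65, "0.5" = 1.45, "0.6" = 1.21, "0.7" = -0.02,
              "0.8" = -0.02, "0.9" = -1.90, "1" = -1.91, "1.5" = -11.29),
    "0.8" = c("0.5" = 1.45, "0.6" = 1.21, "0.7" = -0.02, "0.8" = -0.02,
              "0.9" = -1.90, "1" = -1.91),
    "0.9" = c("0.4" = 1.45, "0.5" = 1.45, "0.6" = 1.21, "0.7" = -0.02,
              "0.8" = -0.02, "0.9" = -1.91, "1" = -1.91),
    "1"   = c("0.5" = 1.43, "0.6" = 1.19, "0.7" = -0.04, "0.8" = -0.04,
              "0.9" = -1.92, "1" = -1.93, "1.5" = -11.30),
    "1.5" = c("0" = 2.69, "0.7" = 0.05, "1.5" = -11.20))),
  "0.5x0.5" = make_sweep(list(
    "0"   = c("0" = 4.06, "0.7" = 1.39, "1.5" = -10.52),
    "0.4" = c("0.5" = 2.30, "0.7" = 0.84, "0.8" = 0.84, "0.9" = -1.09),
    "0.5" = c("0.4" = 2.30, "0.5" = 2.30, "0.6" = 2.07, "0.7" = 0.84,
              "0.8" = 0.84, "0.9" = -1.09, "1" = -1.16),
    "0.6" = c("0.5" = 2.51, "0.6" = 1.95, "0.7" = 0.73, "0.8" = 0.73,
              "0.9" = -1.20, "1" = -1.27),
    "0.7" = c("0" = 3.12, "0.5" = 1.94, "0.6" = 1.70, "0.7" = 0.19,
              "0.8" = 0.19, "0.9" = -1.72, "1" = -1.73, "1.5" = -11.56),
    "0.8" = c("0.5" = 1.94, "0.6" = 1.70, "0.7" = 0.19, "0.8" = 0.19,
              "0.9" = -1.72, "1" = -1.73),
    "0.9" = c("0.4" = 1.04, "0.5" = 1.04, "0.6" = 0.81, "0.7" = -0.63,
              "0.8" = -0.63, "0.9" = -2.53, "1" = -2.54),
    "1"   = c("0.5" = 1.03, "0.6" = 0.80, "0.7" = -0.64, "0.8" = -0.64,
              "0.9" = -2.55, "1" = -2.56, "1.5" = -12.27),
    "1.5" = c("0" = -3.58, "0.7" = -6.01, "1.5" = -16.94))))

#' Packaged reference measured FOF grid
#'
#' Measured microDiamond field output factors for the 49-field design
#' (7 x 7 symmetric rectangular MLC fields, sides 0.5-4 cm), normalized to
#' the 4 x 4 cm2 msr field, for beam quality 6X or 6FFF.
#'
#' @param beam_quality `"6X"` or `"6FFF"`.
#' @return A [fof_grid()] of kind `"measured"`.
#' @export
reference_fof_grid <- function(beam_quality = c("6X", "6FFF")) {
  beam_quality <- match.arg(beam_quality)
  fof_grid(t(ref_fof_x_major[[beam_quality]]), ref_sides, ref_sides,
           "measured", beam_quality)
}

#' Packaged reference difference grid
#'
#' Percent differences between calculated (optimized-ESS beam model) and
#' measured field output factors over the 49-field design.
#'
#' @param beam_quality `"6X"` or `"6FFF"`.
#' @return A [fof_grid()] of kind `"difference_percent"`.
#' @export
reference_diff_grid <- function(beam_quality = c("6X", "6FFF")) {
  beam_quality <- match.arg(beam_quality)
  fof_grid(t(ref_diff_x_major[[beam_quality]]), ref_sides, ref_sides,
           "difference_percent", beam_quality, convention = "as_published")
}

#' Packaged reference ESS sweep tables (6X)
#'
#' Percent calculated-minus-measured FOF differences over candidate
#' (ESSy, ESSx) combinations for the three most informative fields of the
#' design: the two extreme elongated fields 4 x 0.5 and 0.5 x 4 cm2 and the
#' smallest square 0.5 x 0.5 cm2.  Rows are ESSy, columns ESSx (mm); only
#' the evaluated combinations carry values.
#'
#' @return Named list of sparse matrices (`"4x0.5"`, `"0.5x4"`,
#'   `"0.5x0.5"`).
#' @export
reference_ess_sweeps <- function() ref_sweeps_6x

#' Write the packaged reference datasets as CSV fixtures
#'
#' Emits, in the package's grid and sweep CSV dialects: the measured FOF
#' grids (6X, 6FFF), the optimized-ESS difference grids (6X, 6FFF), and the
#' three 6X ESS-sweep tables.  Each file carries provenance comments.
#'
#' @param destination Directory (created if needed).
#' @return Character vector of the written paths, invisibly.
#' @export
emit_fixtures <- function(destination) {
  if (!dir.exists(destination))
    dir.create(destination, recursive = TRUE)
  if (file.access(destination, 2L) != 0L)
    stop("destination not writable: ", destination, call. = FALSE)
  paths <- character()
  for (bq in c("6X", "6FFF")) {
    p <- file.path(destination,
                   sprintf("fof_measured_%s.csv", tolower(bq)))
    write_fof_grid(reference_fof_grid(bq), p, extra_comments =
      "provenance=reference measured dataset, HD-MLC TrueBeam, microDiamond, TRS-483 workflow")
    paths <- c(paths, p)
    p <- file.path(destination,
                   sprintf("fof_diff_optimal_%s.csv", tolower(bq)))
    write_fof_grid(reference_diff_grid(bq), p, extra_comments =
      "provenance=reference calc-minus-meas differences at optimized ESS")
    paths <- c(paths, p)
  }
  sweeps <- reference_ess_sweeps()
  for (fld in names(sweeps)) {
    p <- file.path(destination,
                   sprintf("ess_sweep_6x_%s.csv", gsub("[^0-9x]", "",
                                                       gsub("\\.", "", fld))))
    write_ess_sweep(sweeps[[fld]], p, field = fld, beam_quality = "6X",
                    extra_comments =
      "provenance=reference ESS sweep differences, calc minus meas, percent")
    paths <- c(paths, p)
  }
  invisible(paths)
}
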