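#' Detector reading set for one field
#'
#' Mean of repeated charge readings for a single field setting, with the
#' repeat count and spread kept for bookkeeping.
#'
#' @param field A [field_spec()].
#' @param mean_reading Mean detector signal (arbitrary charge units), > 0.
#' @param n_repeats Number of repeats (typically 3-5).
#' @param reading_sd Standard deviation of the repeats, same units.
#' @return An object of class `reading_set`.
#' @export
reading_set <- function(field, mean_reading, n_repeats = 3L, reading_sd = 0) {
  stopifnot(inherits(field, "field_spec"))
  if (!is.numeric(mean_reading) || mean_reading <= 0)
    stop("'mean_reading' must be positive", call. = FALSE)
  if (n_repeats < 1L) stop("'n_repeats' must be >= 1", call. = FALSE)
  structure(list(field = field, mean_reading = mean_reading,
                 n_repeats = as.integer(n_repeats), reading_sd = reading_sd),
            class = "reading_set")
}

#' Field output factor from a reading ratio and correction factor
#'
#' TRS-483 intermediate-field determination of the field output factor
#' \deqn{\Omega = (M_{clin} / M_{msr}) \cdot k,}
#' the ratio of the test-field to machine-specific-reference-field readings
#' times the detector output correction factor for the equivalent square
#' field size of the test field.  The msr field here is the 4 x 4 cm2
#' MLC-shaped field of the intermediate-field method.
#'
#' @param reading_clin [reading_set()] of the clinical test field.
#' @param reading_msr [reading_set()] of the msr field.
#' @param ocf Output correction factor; must lie in the validity band
#'   `[0.95, 1.05]`.
#' @param esf Optional `equivalent_square` recording which field size drove
#'   the OCF.
#' @return An object of class `fof_measurement` with element `fof`.
#' @export
compute_fof <- function(reading_clin, reading_msr, ocf, esf = NULL) {
  stopifnot(inherits(reading_clin, "reading_set"),
            inherits(reading_msr, "reading_set"))
  if (reading_msr$mean_reading <= 0)
    stop("msr reading must be positive", call. = FALSE)
  if (!is.numeric(ocf) || length(ocf) != 1L || ocf < 0.95 || ocf > 1.05)
    stop(sprintf("OCF %.4f outside the validity band [0.95, 1.05]", ocf),
         call. = FALSE)
  structure(list(field = reading_clin$field, esf = esf, ocf_applied = ocf,
                 fof = reading_clin$mean_reading / reading_msr$mean_reading * ocf),
            class = "fof_measurement")
}

#' @export
print.fof_measurement <- function(x, ...) {
  cat(sprintf("FOF %.5f for field %s cm (OCF %.4f)\n",
              x$fof, x$field$label, x$ocf_applied))
  invisible(x)
}

#' Construct a field-output-factor grid
#'
#' A `fof_grid` is a rectangular matrix of values indexed by the Y (rows) and
#' X (columns) field sides, of kind `"measured"`, `"calculated"` or
#' `"difference_percent"`.
#'
#' @param values Numeric matrix, rows = Y sides, columns = X sides.
#' @param y_sides_cm,x_sides_cm Strictly increasing axes, cm.
#' @param kind Grid kind.
#' @param beam_quality Beam quality label.
#' @param msr_side_cm Side of the machine-specific reference (msr) field;
#'   default 4.
#' @param convention For difference grids, `"relative"` (percent of the
#'   measured value) or `"absolute"` (percentage points).
#' @return An object of class `fof_grid`.
#' @export
fof_grid <- function(values, y_sides_cm = default_field_sides(),
                     x_sides_cm = default_field_sides(),
                     kind = c("measured", "calculated", "difference_percent"),
                     beam_quality = "6X", msr_side_cm = 4,
                     convention = "relative") {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (any(diff(y_sides_cm) <= 0) || any(diff(x_sides_cm) <= 0))
    stop("grid axes must be strictly increasing", call. = FALSE)
  if (nrow(values) != length(y_sides_cm) || ncol(values) != length(x_sides_cm))
    stop("values matrix does not match the axes", call. = FALSE)
  dimnames(values) <- list(format(y_sides_cm), format(x_sides_cm))
  if (kind != "difference_percent") {
    finite <- values[is.finite(values)]
    if (length(finite) && (any(finite <= 0) || any(finite > 1.2)))
      stop("output factors must lie in (0, 1.2]", call. = FALSE)
  }
  structure(list(values = values, y_sides_cm = y_sides_cm,
                 x_sides_cm = x_sides_cm, kind = kind,
                 beam_quality = beam_quality, msr_side_cm = msr_side_cm,
                 convention = if (kind == "difference_percent") convention
                              else NULL),
            class = "fof_grid")
}

#' The seven field sides of the reference measurement design
#'
#' @return `c(0.5, 1, 1.5, 2, 2.5, 3, 4)` (cm) -- 49 field settings in all.
#' @export
default_field_sides <- function() c(0.5, 1, 1.5, 2, 2.5, 3, 4)

#' @export
print.fof_grid <- function(x, ...) {
  cat(sprintf("FOF grid (%s%s), %s, %d x %d fields (Y rows, X columns)\n",
              x$kind,
              if (!is.null(x$convention)) paste0(", ", x$convention) else "",
              x$beam_quality, nrow(x$values), ncol(x$values)))
  print(round(x$values, 4))
  invisible(x)
}

grid_cell_index <- function(grid, y_cm, x_cm) {
  iy <- which(abs(grid$y_sides_cm - y_cm) < 1e-9)
  ix <- which(abs(grid$x_sides_cm - x_cm) < 1e-9)
  if (length(iy) != 1L || length(ix) != 1L)
    stop(sprintf("field side (%g, %g) cm is not on the grid axes", y_cm, x_cm),
         call. = FALSE)
  c(iy, ix)
}

#' Assemble a grid from individual FOF measurements
#'
#' Places each measurement in its (Y, X) cell; duplicate cells are an error,
#' cells with no measurement are reported as gaps (and left `NA`).
#'
#' @param measurements List of `fof_measurement` objects.
#' @param y_sides_cm,x_sides_cm Grid axes, cm.
#' @param kind `"measured"` or `"calculated"`.
#' @param beam_quality Beam quality label.
#' @return A list with elements `grid` (the `fof_grid`) and `gaps` (data
#'   frame of unfilled cells, zero rows when complete).
#' @export
build_fof_grid <- function(measurements,
                           y_sides_cm = default_field_sides(),
                           x_sides_cm = default_field_sides(),
                           kind = "measured", beam_quality = "6X") {
  vals <- matrix(NA_real_, length(y_sides_cm), length(x_sides_cm))
  skeleton <- fof_grid(matrix(1, length(y_sides_cm), length(x_sides_cm)),
                       y_sides_cm, x_sides_cm, kind, beam_quality)
  for (m in measurements) {
    stopifnot(inherits(m, "fof_measurement"))
    ij <- grid_cell_index(skeleton, m$field$y_cm, m$field$x_cm)
    if (!is.na(vals[ij[1L], ij[2L]]))
      stop(sprintf("duplicate measurement for field (%g, %g) cm",
                   m$field$y_cm, m$field$x_cm), call. = FALSE)
    vals[ij[1L], ij[2L]] <- m$fof
  }
  gaps <- which(is.na(vals), arr.ind = TRUE)
  gaps <- data.frame(y_cm = y_sides_cm[gaps[, 1L]],
                     x_cm = x_sides_cm[gaps[, 2L]])
  list(grid = fof_grid(vals, y_sides_cm, x_sides_cm, kind, beam_quality),
       gaps = gaps)
}

#' Cellwise percent difference between two grids
#'
#' Forms the calculated-minus-measured difference grid.  Under the default
#' `"relative"` convention the cell is `100 * (calc - meas) / meas`; under
#' `"absolute"` it is `100 * (calc - meas)` (percentage points of the output
#' factor).  At output factors near 1 the two coincide; near 0.64 they do
#' not, so the convention is recorded on the result.
#'
#' @param calc,meas Complete `fof_grid`s of kind `"calculated"` and
#'   `"measured"` on identical axes.
#' @param convention `"relative"` or `"absolute"`.
#' @return A `fof_grid` of kind `"difference_percent"`.
#' @export
difference_grid <- function(calc, meas,
                            convention = c("relative", "absolute")) {
  convention <- match.arg(convention)
  stopifnot(inherits(calc, "fof_grid"), inherits(meas, "fof_grid"))
  if (!isTRUE(all.equal(calc$y_sides_cm, meas$y_sides_cm)) ||
      !isTRUE(all.equal(calc$x_sides_cm, meas$x_sides_cm)))
    stop("grid axes differ", call. = FALSE)
  if (anyNA(calc$values) || anyNA(meas$values))
    stop("difference requires complete grids", call. = FALSE)
  d <- if (convention == "relative")
    100 * (calc$values - meas$values) / meas$values
  else
    100 * (calc$values - meas$values)
  fof_grid(d, calc$y_sides_cm, calc$x_sides_cm, "difference_percent",
           calc$beam_quality, calc$msr_side_cm, convention)
}

#' Summary statistics of a difference grid
#'
#' Mean, sample standard deviation (n - 1), minimum and maximum of the
#' cellwise percent differences, the form in which agreement between
#' calculated and measured output factors is conventionally reported.  The
#' msr cell is identically zero by construction (both grids are normalized
#' there); `exclude_msr` removes it from the statistics.
#'
#' @param diff A complete `fof_grid` of kind `"difference_percent"`.
#' @param exclude_msr Drop the msr (reference) cell.
#' @return An object of class `diff_summary` with elements `mean_pct`,
#'   `sd_pct`, `min_pct`, `max_pct`, `n_cells`, `excluded_msr`.
#' @export
summarize_diff <- function(diff, exclude_msr = FALSE) {
  stopifnot(inherits(diff, "fof_grid"))
  if (diff$kind != "difference_percent")
    stop("'diff' must be a difference grid", call. = FALSE)
  v <- diff$values
  if (anyNA(v)) stop("difference grid is incomplete", call. = FALSE)
  if (exclude_msr) {
    ij <- grid_cell_index(diff, diff$msr_side_cm, diff$msr_side_cm)
    v <- v[-((ij[2L] - 1L) * nrow(v) + ij[1L])]
  }
  v <- as.numeric(v)
  if (!length(v)) stop("no cells to summarize", call. = FALSE)
  structure(list(mean_pct = mean(v), sd_pct = stats::sd(v),
                 min_pct = min(v), max_pct = max(v), n_cells = length(v),
                 excluded_msr = exclude_msr,
                 convention = diff$convention,
                 beam_quality = diff$beam_quality),
            class = "diff_summary")
}

#' @export
print.diff_summary <- function(x, ...) {
  cat(sprintf("%s: %s%% +/- %s%% (1SD), range [%s%%, %s%%], n = %d%s\n",
              x$beam_quality,
              round_half_away(x$mean_pct, 1), round_half_away(x$sd_pct, 1),
              round_half_away(x$min_pct, 1), round_half_away(x$max_pct, 1),
              x$n_cells,
              if (x$excluded_msr) " (msr cell excluded)" else ""))
  invisible(x)
}

# Display rounding: half away from zero (report convention); internal values
# keep full precision.
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Differences at the two extreme elongated fields
#'
#' Returns the difference-grid cells of the two most elongated fields of the
#' design, `(Y = 4, X = 0.5)` first and `(Y = 0.5, X = 4)` second -- the two
#' cells whose calculated-minus-measured differences drive the effective spot
#' size optimization (ESSx via the X = 0.5 cm field, ESSy via the Y = 0.5 cm
#' field).
#'
#' @param diff A `fof_grid` of kind `"difference_percent"`.
#' @param short_side_cm,long_side_cm The elongated field sides; defaults 0.5
#'   and 4 cm.
#' @return Named numeric vector `c(y4_x05 = ..., y05_x4 = ...)` in percent.
#' @export
extreme_field_differences <- function(diff, short_side_cm = 0.5,
                                      long_side_cm = 4) {
  stopifnot(inherits(diff, "fof_grid"))
  ij1 <- grid_cell_index(diff, long_side_cm, short_side_cm)
  ij2 <- grid_cell_index(diff, short_side_cm, long_side_cm)
  v1 <- diff$values[ij1[1L], ij1[2L]]
  v2 <- diff$values[ij2[1L], ij2[2L]]
  if (is.na(v1) || is.na(v2))
    stop("extreme field cell missing from the grid", call. = FALSE)
  c(y4_x05 = unname(v1), y05_x4 = unname(v2))
}
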